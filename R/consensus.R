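# Consensus-sequence screening of candidate (weak-evidence) binding sites.

#' Check the palindromic consensus criterion
#'
#' A 22-nt candidate core passes when it carries G at positions 5 and 7 and
#' C at positions 16 and 18 (1-based), the four positions of the palindromic
#' CRP consensus -NNNTGTGANNNNNNTCACANNN- that contribute most of the
#' binding free energy. Only these four positions are enforced; the rest of
#' the palindrome is not scored.
#'
#' @param seqs character vector or `DNAStringSet` of 22-nt sequences.
#' @return named logical vector; errors if any sequence is not 22 nt.
#' @export
consensusCheck <- function(seqs) {
  s <- toupper(as.character(seqs))
  if (any(nchar(s) != 22)) {
    stop("consensusCheck requires sequences of exactly 22 nt (got length ",
         paste(unique(nchar(s)[nchar(s) != 22]), collapse = ", "), ")")
  }
  res <- substr(s, 5, 5) == "G" & substr(s, 7, 7) == "G" &
         substr(s, 16, 16) == "C" & substr(s, 18, 18) == "C"
  names(res) <- names(seqs)
  res
}

#' Screen candidate sites by consensus and predict their roles
#'
#' Annotates every candidate with the consensus flag and, for sites passing
#' the criterion, with the roles assigned by both the SVM model and the rule
#' set; disagreements between the two predictors are flagged, never
#' suppressed. The input roles are not altered — the report is an
#' append-only annotation.
#'
#' @param weakSites a [SiteSet-class] of candidate (typically weak-evidence)
#'   sites; extended automatically when needed.
#' @param model a [CrpModel-class], or NULL to skip model predictions.
#' @param ruleset a [RuleSet-class], default [canonicalRuleset()].
#' @param spec descriptor layout for the model features.
#' @param k flank length used if the sites still need extension.
#' @return data.frame with one row per candidate: `site_id`, `gene`,
#'   `passes_consensus`, `model_role`, `model_score`, `ruleset_role`,
#'   `matched_rules`, `disagreement`. Non-passing sites keep NA predictions.
#' @export
screenCandidates <- function(weakSites, model = NULL,
                             ruleset = canonicalRuleset(),
                             spec = descriptorSpec(), k = 10L) {
  stopifnot(is(weakSites, "SiteSet"))
  info <- siteInfo(weakSites)
  n <- nrow(info)
  if (n == 0) {
    return(data.frame(site_id = character(), gene = character(),
                      passes_consensus = logical(),
                      model_role = character(), model_score = numeric(),
                      ruleset_role = character(), matched_rules = character(),
                      disagreement = logical(), stringsAsFactors = FALSE))
  }
  passes <- unname(consensusCheck(coreSeqs(weakSites)))
  out <- data.frame(site_id = info$site_id, gene = info$gene,
                    passes_consensus = passes,
                    model_role = NA_character_, model_score = NA_real_,
                    ruleset_role = NA_character_,
                    matched_rules = NA_character_,
                    disagreement = NA, stringsAsFactors = FALSE)
  if (!any(passes)) return(out)
  cand <- weakSites[which(passes)]
  if (!length(extendedSeqs(cand))) cand <- extendSites(cand, k = k)
  rf <- ruleFeatures(cand, sequence = spec@motifSequence)
  ruleRes <- applyRuleset(rf, ruleset)
  out$ruleset_role[passes] <- ruleRes$role
  out$matched_rules[passes] <- ruleRes$matched
  if (!is.null(model)) {
    feats <- extractFeatures(cand, spec)
    pred <- predictRoles(model, feats)
    out$model_role[passes] <- pred$labels
    out$model_score[passes] <- pred$scores
    out$disagreement[passes] <- pred$labels != ruleRes$role &
      ruleRes$role != "uncovered"
  }
  out
}
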