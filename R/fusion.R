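# Naive-Bayes fusion of the two branch scores.
#
# Both branches are trained on class-balanced data, so each branch score
# is read as a class posterior at prior 1/2.  Under conditional
# independence the combined posterior odds are the product of the two
# branch likelihood-ratio terms times the prior odds:
#   odds = (pi/(1-pi)) * (o1/(1-o1)) * (o2/(1-o2)),  fused = odds/(1+odds).
# At pi = 0.5 this reduces to o1*o2 / (o1*o2 + (1-o1)(1-o2)).

#' Fusion configuration
#' @param prior class prior pi in (0,1); default 0.5 (balanced training).
#' @param threshold call threshold in (0,1); default 0.5.
#' @return object of class \code{FusionConfig}.
#' @export
fusion_config <- function(prior = 0.5, threshold = 0.5) {
  if (!is.numeric(prior) || prior <= 0 || prior >= 1)
    abort2("prior must lie in (0,1)", "morfmlp_config_error")
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1)
    abort2("threshold must lie in (0,1)", "morfmlp_config_error")
  structure(list(prior = prior, threshold = threshold),
            class = "FusionConfig")
}

#' Fuse two branch scores by the Bayes rule
#'
#' @param o1,o2 numeric score vectors in [0,1] (clipped internally to
#'   [1e-7, 1-1e-7]).
#' @param config a \code{\link{fusion_config}} (or a bare prior).
#' @return fused scores in (0,1).  Strictly increasing in each argument,
#'   symmetric, with 0.5 as the neutral element at the default prior.
#' @export
fuse <- function(o1, o2, config = fusion_config()) {
  if (is.numeric(config)) config <- fusion_config(prior = config)
  eps <- 1e-7
  o1 <- pmin(pmax(o1, eps), 1 - eps)
  o2 <- pmin(pmax(o2, eps), 1 - eps)
  pi_ <- config$prior
  log_odds <- log(pi_ / (1 - pi_)) + log(o1 / (1 - o1)) + log(o2 / (1 - o2))
  1 / (1 + exp(-log_odds))
}

#' Threshold fused scores into binary calls
#' @param scores numeric scores.
#' @param threshold call = 1 iff score >= threshold.
#' @return integer 0/1 vector.
#' @export
call_scores <- function(scores, threshold = 0.5) {
  as.integer(scores >= threshold)
}
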