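#' Spearman correlation between a predicted profile and literature frequencies
#'
#' Computes Spearman's rho (average ranks for ties) between a disease's
#' NAAS vector and its literature co-occurrence frequencies over the shared
#' cytokines, with a two-sided p-value from one of three null models:
#' `exact` enumerates every permutation (feasible for length <= 10),
#' `permutation` is seeded Monte-Carlo, and `asymptotic` uses the
#' t-approximation `t = rho * sqrt((n - 2) / (1 - rho^2))`. `auto` picks
#' exact for n <= 10 and asymptotic otherwise. A constant input vector has
#' no defined rank correlation and is returned flagged rather than as an
#' error.
#'
#' @param naas_vec,lit_freq_vec aligned numeric vectors (length >= 3).
#' @param mode p-value mode; see above.
#' @param n_perm Monte-Carlo permutation count (default 1e5).
#' @param seed integer seed for the permutation mode.
#' @return List: `rho`, `p_value`, `n`, `mode`, `constant` (flag).
#' @export
spearman_validate <- function(naas_vec, lit_freq_vec,
                              mode = c("auto", "exact", "permutation",
                                       "asymptotic"),
                              n_perm = 1e5, seed = 1) {
  mode <- match.arg(mode)
  if (length(naas_vec) != length(lit_freq_vec))
    stopf("vectors must be aligned")
  n <- length(naas_vec)
  if (n < 3) stopf("need at least 3 shared cytokines (got %d)", n)
  rx <- rank(naas_vec); ry <- rank(lit_freq_vec)
  if (length(unique(rx)) == 1 || length(unique(ry)) == 1)
    return(list(rho = NA_real_, p_value = NA_real_, n = n, mode = mode,
                constant = TRUE))
  rho <- cor(rx, ry)
  if (mode == "auto") mode <- if (n <= 10) "exact" else "asymptotic"
  p <- switch(mode,
    exact = {
      if (n > 10) stopf("exact enumeration only for length <= 10")
      cpp_spearman_exact_p(rx, ry)
    },
    permutation = {
      rxc <- rx - mean(rx)
      obs <- abs(sum(rxc * ry))
      with_seed(seed, {
        hits <- 0L
        block <- 10000L
        left <- as.integer(n_perm)
        while (left > 0L) {
          b <- min(block, left)
          perm <- vapply(seq_len(b), function(i) ry[sample.int(n)],
                         numeric(n))
          hits <- hits + sum(abs(crossprod(rxc, perm)) >= obs - 1e-9)
          left <- left - b
        }
        (1 + hits) / (n_perm + 1)
      })
    },
    asymptotic = {
      if (abs(rho) >= 1) 0 else {
        tt <- rho * sqrt((n - 2) / (1 - rho^2))
        2 * pt(-abs(tt), df = n - 2)
      }
    })
  list(rho = rho, p_value = p, n = n, mode = mode, constant = FALSE)
}

#' Validate all disease profiles against a literature frequency table
#'
#' Aligns each disease's NAAS with its sampled literature frequencies on
#' the shared cytokines and applies [spearman_validate()].
#'
#' @param profiles a `cytokine_profiles` object.
#' @param lit_freq long data.frame (`disease_id`, `cytokine`, `frequency`).
#' @param mode,n_perm,seed passed to [spearman_validate()].
#' @param min_shared minimum shared cytokines required (default 3).
#' @return data.frame: `disease_id`, `rho`, `p_value`, `n_cytokines`,
#'   `constant`.
#' @export
validate_profiles <- function(profiles, lit_freq, mode = "asymptotic",
                              n_perm = 1e5, seed = 1, min_shared = 3) {
  naas <- profiles$naas
  shared_dis <- intersect(rownames(naas), unique(lit_freq$disease_id))
  rows <- lapply(shared_dis, function(d) {
    sub <- lit_freq[lit_freq$disease_id == d, ]
    cyto <- intersect(colnames(naas), sub$cytokine)
    if (length(cyto) < min_shared) return(NULL)
    v <- spearman_validate(naas[d, cyto],
                           sub$frequency[match(cyto, sub$cytokine)],
                           mode = mode, n_perm = n_perm, seed = seed)
    data.frame(disease_id = d, rho = v$rho, p_value = v$p_value,
               n_cytokines = v$n, constant = v$constant,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(disease_id = character(), rho = numeric(),
                      p_value = numeric(), n_cytokines = integer(),
                      constant = logical())
  rownames(out) <- NULL
  out
}

#' Bonferroni-corrected significance cutoff
#'
#' `alpha / n_tests`, optionally rounded to a number of significant digits
#' for reporting (0.05 / 171 rounds to 0.0003 at one significant digit).
#'
#' @param alpha family-wise level (default 0.05).
#' @param n_tests number of tests (>= 1).
#' @param signif_digits optional rounding, e.g. 1.
#' @return The corrected cutoff.
#' @export
corrected_cutoff <- function(alpha = 0.05, n_tests, signif_digits = NULL) {
  if (n_tests < 1) stopf("n_tests must be >= 1")
  x <- alpha / n_tests
  if (!is.null(signif_digits)) x <- signif(x, signif_digits)
  x
}

#' Count validated diseases
#'
#' A disease validates when its profile correlates positively with the
#' literature (`rho > 0`) at `p_value < cutoff`.
#'
#' @param results data.frame from [validate_profiles()].
#' @param cutoff p-value cutoff (e.g. from [corrected_cutoff()]).
#' @param require_positive also require `rho > 0` (default `TRUE`).
#' @return Number of validated diseases.
#' @export
count_validated <- function(results, cutoff, require_positive = TRUE) {
  if (!nrow(results)) return(0L)
  ok <- !is.na(results$p_value) & results$p_value < cutoff
  if (require_positive) ok <- ok & !is.na(results$rho) & results$rho > 0
  sum(ok)
}

#' Known-cytokine flags from literature frequencies
#'
#' A cytokine counts as a known association of a disease when its
#' literature sampling frequency reaches `freq_cutoff` (default 0.005).
#'
#' @param freq_vec named numeric frequencies.
#' @param freq_cutoff threshold (default 0.005).
#' @return Named logical vector.
#' @export
known_from_frequency <- function(freq_vec, freq_cutoff = 0.005) {
  freq_vec >= freq_cutoff
}

#' Recall of known cytokines at a NAAS cutoff
#'
#' Of the cytokines flagged as known for a disease, how many exceed the
#' NAAS cutoff (strictly)? NAAS never reaches 1, so a cutoff of 1 always
#' gives zero hits.
#'
#' @param naas_vec named NAAS values.
#' @param known_flags aligned logical flags (see [known_from_frequency()]).
#' @param naas_cutoff strict NAAS threshold (default 0.8).
#' @return List: `hits`, `known`, `recall` (`NA` and flagged when no
#'   cytokine is known).
#' @export
recall_at_cutoff <- function(naas_vec, known_flags, naas_cutoff = 0.8) {
  if (length(naas_vec) != length(known_flags))
    stopf("naas_vec and known_flags must be aligned")
  known <- sum(known_flags)
  hits <- sum(known_flags & naas_vec > naas_cutoff)
  list(hits = hits, known = known,
       recall = if (known == 0) NA_real_ else hits / known,
       undefined = known == 0)
}
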