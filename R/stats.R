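# Inferential machinery: exact Wilcoxon signed-rank tests (full enumeration
# of the sign-flip null), r-equivalent effect sizes, Benjamini-Hochberg FDR,
# trial-label permutation tests, the distance-decay regression and the 2x2
# interaction contrast. With eight hemispheres every signed-rank p-value is
# a discrete quantile of the 256-point null, which is what makes the group
# statistics exactly reproducible.

# Exact null distribution of the signed-rank sum for the given (possibly
# tie-averaged) ranks: probabilities of 2*W on the half-integer grid
# 0, 0.5, ..., sum(ranks). Dynamic-programming convolution over sign flips.
signed_rank_null <- function(ranks) {
  g <- round(ranks * 2)              # ranks in half-units are integers
  total <- sum(g)
  probs <- numeric(total + 1)
  probs[1] <- 1
  for (r in g) {
    shifted <- c(numeric(r), probs[seq_len(total + 1 - r)])
    probs <- (probs + shifted) / 2
  }
  probs                              # probs[k+1] = P(2W = k)
}

#' Exact Wilcoxon signed-rank test
#'
#' Paired test on `values_a - values_b` (or on a single vector of
#' differences against zero). Absolute differences are ranked (average ranks
#' for ties), W is the smaller of the two signed rank sums, and the
#' two-sided p-value is `2 P(W_null <= W)` from complete enumeration of all
#' `2^N` sign assignments, capped at 1. Zero differences are dropped with a
#' warning. The effect size is the r-equivalent correlation.
#'
#' @param values_a numeric vector (e.g. per-hemisphere alHG values), or
#'   paired differences if `values_b` is missing.
#' @param values_b optional second sample, paired with `values_a`.
#' @return An `hgalpha_test` list: `statistic` (W), `p`, `r_e`, `n`,
#'   `method`.
#' @export
exact_signed_rank <- function(values_a, values_b = NULL) {
  d <- if (is.null(values_b)) values_a else values_a - values_b
  if (!is.null(values_b) && length(values_a) != length(values_b)) {
    stop_invalid("paired samples must have equal length")
  }
  if (any(d == 0)) {
    warning(sum(d == 0), " zero difference(s) dropped")
    d <- d[d != 0]
  }
  n <- length(d)
  if (n < 2) stop_invalid("need at least 2 nonzero paired differences")
  if (n > 20) stop_invalid("exact enumeration limited to N <= 20")
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  w_neg <- sum(r[d < 0])
  w <- min(w_pos, w_neg)
  probs <- signed_rank_null(r)
  # P(W_null <= w): grid is in half-units of W
  k <- floor(w * 2 + .grid_eps)
  p <- min(1, 2 * sum(probs[seq_len(k + 1)]))
  structure(list(statistic = w, p = p, r_e = r_equivalent(p, n), n = n,
                 method = "exact Wilcoxon signed rank"),
            class = "hgalpha_test")
}

#' @export
print.hgalpha_test <- function(x, ...) {
  cat(sprintf("%s: N = %d, W = %g, p = %.4g, r_e = %.3f\n",
              x$method, x$n, x$statistic, x$p, x$r_e))
  invisible(x)
}

#' r-equivalent effect size
#'
#' Converts a two-sided p-value and sample size into the equivalent
#' Pearson correlation: the one-tailed p is mapped to a t quantile with
#' `n - 1` degrees of freedom and `r_e = sqrt(t^2 / (t^2 + df))`.
#'
#' @param p_two_sided two-sided p-value in (0, 1].
#' @param n sample size (>= 3 for a meaningful value).
#' @return r-equivalent in \[0, 1).
#' @export
r_equivalent <- function(p_two_sided, n) {
  if (any(p_two_sided <= 0)) stop_invalid("p must be positive")
  if (any(p_two_sided > 1)) stop_invalid("p must not exceed 1")
  df <- n - 1
  t <- qt(1 - p_two_sided / 2, df)
  unname(sqrt(t^2 / (t^2 + df)))
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up false-discovery-rate control at level `q`.
#'
#' @param p_values vector of p-values in (0, 1].
#' @param q FDR level.
#' @return Logical significance mask (empty input gives an empty mask).
#' @export
fdr_correct <- function(p_values, q = 0.05) {
  if (!length(p_values)) return(logical(0))
  p.adjust(p_values, method = "BH") <= q
}

#' Trial-label permutation test
#'
#' Tests the difference of group means between two sets of single-trial
#' values by shuffling the group labels; the p-value is
#' `(1 + #{|perm| >= |obs|}) / (n_perm + 1)`.
#'
#' @param trial_values_a,trial_values_b single-trial values per group (at
#'   least 5 trials each).
#' @param n_perm number of label permutations.
#' @param seed integer seed.
#' @return An `hgalpha_test` list with `statistic` (observed mean
#'   difference), `p`, `n`.
#' @export
trial_label_permutation <- function(trial_values_a, trial_values_b,
                                    n_perm = 1000, seed = 1) {
  na <- length(trial_values_a); nb <- length(trial_values_b)
  if (na < 5 || nb < 5) stop_invalid("need at least 5 trials per group")
  pooled <- c(trial_values_a, trial_values_b)
  obs <- mean(trial_values_a) - mean(trial_values_b)
  if (sd(pooled) == 0) {
    warning("degenerate constant data; p = 1")
    return(structure(list(statistic = obs, p = 1, r_e = 0, n = na + nb,
                          method = "trial-label permutation"),
                     class = "hgalpha_test"))
  }
  old <- save_rng(); on.exit(restore_rng(old))
  set.seed(seed)
  perm <- replicate(n_perm, {
    idx <- sample.int(na + nb, na)
    mean(pooled[idx]) - mean(pooled[-idx])
  })
  p <- (1 + sum(abs(perm) >= abs(obs) - .grid_eps)) / (n_perm + 1)
  structure(list(statistic = obs, p = p, r_e = NA_real_, n = na + nb,
                 method = "trial-label permutation"),
            class = "hgalpha_test")
}

#' Distance-decay regression of alpha suppression
#'
#' For each hemisphere, fits ordinary least squares of per-contact
#' baseline-corrected alpha power on Euclidean distance from the mean
#' coordinate of that hemisphere's alHG contacts (taken from the
#' localization assignment, not from simulation ground truth), then tests
#' the per-hemisphere slopes against zero with the exact signed-rank test.
#'
#' @param contacts a [make_contact_set()]-style table (contact_id,
#'   hemisphere_id, x, y, z).
#' @param alpha_db named per-contact vector of baseline-corrected alpha
#'   power (dB); names must match contact ids.
#' @param assigned named per-contact assignment vector ("pmHG"/"alHG"/NA)
#'   used to locate each hemisphere's alHG centroid.
#' @return A `distance_decay_fit` list: `per_hemisphere` data.frame
#'   (hemisphere_id, slope, intercept, n_contacts), `group_test`
#'   (an `hgalpha_test` of slopes vs 0), and a per-contact table
#'   (`contact_table`: hemisphere_id, contact_id, distance, alpha_db).
#' @export
distance_decay_fit <- function(contacts, alpha_db, assigned) {
  stopifnot(!is.null(names(alpha_db)))
  hems <- unique(contacts$hemisphere_id)
  per <- list(); tabs <- list()
  for (h in hems) {
    hc <- contacts[contacts$hemisphere_id == h, ]
    al_ids <- hc$contact_id[assigned[hc$contact_id] %in% "alHG"]
    if (length(al_ids) == 0) {
      warning("hemisphere ", h, " has no alHG contacts; excluded")
      next
    }
    centroid <- colMeans(hc[hc$contact_id %in% al_ids, c("x", "y", "z")])
    d <- sqrt((hc$x - centroid[1])^2 + (hc$y - centroid[2])^2 +
                (hc$z - centroid[3])^2)
    y <- alpha_db[hc$contact_id]
    keep <- is.finite(d) & is.finite(y)
    if (sum(keep) < 3) {
      warning("hemisphere ", h, " has fewer than 3 usable contacts; excluded")
      next
    }
    fit <- lm(y[keep] ~ d[keep])
    per[[h]] <- data.frame(hemisphere_id = h,
                           slope = unname(coef(fit)[2]),
                           intercept = unname(coef(fit)[1]),
                           n_contacts = sum(keep))
    tabs[[h]] <- data.frame(hemisphere_id = h,
                            contact_id = hc$contact_id[keep],
                            distance = d[keep], alpha_db = unname(y[keep]))
  }
  per_df <- do.call(rbind, per)
  rownames(per_df) <- NULL
  group <- if (all(abs(per_df$slope) < 1e-10)) {
    warning("all slopes are exactly zero; degenerate group test")
    structure(list(statistic = 0, p = 1, r_e = 0, n = nrow(per_df),
                   method = "exact Wilcoxon signed rank"),
              class = "hgalpha_test")
  } else {
    exact_signed_rank(per_df$slope)
  }
  structure(list(per_hemisphere = per_df,
                 group_test = group,
                 contact_table = do.call(rbind, tabs)),
            class = "distance_decay_fit")
}

#' Stimulus-by-region interaction contrast
#'
#' Per hemisphere, computes
#' `(alHG_clear - alHG_vocoded) - (pmHG_clear - pmHG_vocoded)` from a table
#' of cell means and tests the contrasts against zero with the exact
#' signed-rank test. Hemispheres with a missing cell are excluded.
#'
#' @param cell_means data.frame with columns hemisphere_id, region
#'   ("pmHG"/"alHG"), condition ("clear"/"vocoded"), value.
#' @return An `hgalpha_test`; the per-hemisphere contrasts are attached as
#'   attribute `"contrasts"`.
#' @export
interaction_contrast <- function(cell_means) {
  need <- expand.grid(region = c("pmHG", "alHG"),
                      condition = c("clear", "vocoded"),
                      stringsAsFactors = FALSE)
  hems <- unique(cell_means$hemisphere_id)
  contrasts <- vapply(hems, function(h) {
    sub <- cell_means[cell_means$hemisphere_id == h, ]
    cell <- function(r, cond) {
      v <- sub$value[sub$region == r & sub$condition == cond]
      if (length(v) != 1) NA_real_ else v
    }
    (cell("alHG", "clear") - cell("alHG", "vocoded")) -
      (cell("pmHG", "clear") - cell("pmHG", "vocoded"))
  }, numeric(1))
  if (anyNA(contrasts)) {
    warning(sum(is.na(contrasts)), " hemisphere(s) with missing cells excluded")
    contrasts <- contrasts[!is.na(contrasts)]
  }
  if (all(contrasts == 0)) {
    warning("all interaction contrasts are zero; degenerate test")
    out <- structure(list(statistic = 0, p = 1, r_e = 0,
                          n = length(contrasts),
                          method = "exact Wilcoxon signed rank"),
                     class = "hgalpha_test")
  } else {
    out <- exact_signed_rank(contrasts)
  }
  attr(out, "contrasts") <- contrasts
  out
}

#' Tidy export of test results
#'
#' @param tests named list of `hgalpha_test` objects.
#' @param path optional CSV path.
#' @param q FDR level for the corrected significance flag.
#' @return data.frame: comparison, n, w, p, r_e, significant_fdr.
#' @export
test_results_table <- function(tests, path = NULL, q = 0.05) {
  df <- do.call(rbind, lapply(names(tests), function(nm) {
    t <- tests[[nm]]
    data.frame(comparison = nm, n = t$n, w = t$statistic, p = t$p,
               r_e = t$r_e, stringsAsFactors = FALSE)
  }))
  df$significant_fdr <- fdr_correct(df$p, q)
  if (!is.null(path)) write.csv(df, path, row.names = FALSE)
  df
}
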