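#' Cohen's kappa for two codings of the same cells
#'
#' Chance-corrected agreement between two categorical codings:
#' `kappa = (p_o - p_e) / (1 - p_e)` with `p_o` the exact-match proportion
#' and `p_e` expected agreement from the two marginal category
#' distributions. The Z statistic tests kappa against zero using the
#' classical null-hypothesis standard error
#' `SE0 = sqrt(p_e + p_e^2 - sum_i p1i p2i (p1i + p2i)) / ((1 - p_e) sqrt(N))`.
#'
#' @param coding1,coding2 equal-length vectors of categorical labels
#'   (canonical state-set strings for matrix cells).
#' @return list with `kappa`, `z`, `p_value` (two-sided normal), `p_o`,
#'   `p_e`, `n`; `kappa` is `NA` (flagged) when only one category occurs.
#' @export
cohens_kappa <- function(coding1, coding2) {
  stopifnot(length(coding1) == length(coding2))
  n <- length(coding1)
  cats <- sort(unique(c(coding1, coding2)))
  if (length(cats) < 2L) {
    warning("only one category present; kappa undefined")
    return(list(kappa = NA_real_, z = NA_real_, p_value = NA_real_,
                p_o = 1, p_e = 1, n = n, undefined = TRUE))
  }
  p1 <- table(factor(coding1, cats)) / n
  p2 <- table(factor(coding2, cats)) / n
  p_o <- mean(coding1 == coding2)
  p_e <- sum(p1 * p2)
  kappa <- (p_o - p_e) / (1 - p_e)
  se0 <- sqrt(p_e + p_e^2 - sum(p1 * p2 * (p1 + p2))) / ((1 - p_e) * sqrt(n))
  z <- kappa / se0
  list(kappa = kappa, z = z, p_value = 2 * stats::pnorm(-abs(z)),
       p_o = p_o, p_e = p_e, n = n, undefined = FALSE)
}

#' Inter-rater reliability of two matrix codings
#'
#' Compares two codings of the same specimens-by-characters grid: Cohen's
#' kappa with its Z statistic on the categorical cell labels (a cell is one
#' category given by its canonical state-set string, so `{0,1}` vs `{1}`
#' counts as a disagreement, not partial credit), the exact-match
#' disagreement count, and the Pearson product-moment correlation between
#' the paired numeric cell scores (where partial credit lives).
#'
#' @param coding1,coding2 two [character_matrix()] objects over identical
#'   (specimen, character) grids, or two equal-dimension numeric/character
#'   matrices.
#' @return object of class `reliability`: `kappa`, `z`, `n_disagreements`,
#'   `pearson_rho`, `rho_p_value`, `n_cells`.
#' @export
compare_codings <- function(coding1, coding2) {
  if (inherits(coding1, "character_matrix")) {
    stopifnot(inherits(coding2, "character_matrix"),
              identical(dim(coding1), dim(coding2)))
    if (!identical(coding1$taxa, coding2$taxa) ||
        !identical(coding1$chars$char_id, coding2$chars$char_id))
      stop("the two codings must cover the same specimens and characters ",
           "in the same order")
    keys1 <- vapply(coding1$cells, cell_key, character(1))
    keys2 <- vapply(coding2$cells, cell_key, character(1))
    sc1 <- vapply(coding1$cells, cell_score, numeric(1))
    sc2 <- vapply(coding2$cells, cell_score, numeric(1))
  } else {
    stopifnot(identical(dim(coding1), dim(coding2)))
    keys1 <- as.character(coding1); keys2 <- as.character(coding2)
    sc1 <- suppressWarnings(as.numeric(coding1))
    sc2 <- suppressWarnings(as.numeric(coding2))
  }
  kp <- cohens_kappa(keys1, keys2)
  disagree <- sum(keys1 != keys2)
  ok <- !is.na(sc1) & !is.na(sc2)
  rho <- NA_real_; rho_p <- NA_real_
  if (sum(ok) >= 3L && stats::sd(sc1[ok]) > 0 && stats::sd(sc2[ok]) > 0) {
    ct <- stats::cor.test(sc1[ok], sc2[ok])
    rho <- unname(ct$estimate); rho_p <- ct$p.value
  }
  structure(list(kappa = kp$kappa, z = kp$z, kappa_p_value = kp$p_value,
                 n_disagreements = disagree, pearson_rho = rho,
                 rho_p_value = rho_p, n_cells = length(keys1)),
            class = "reliability")
}

#' @export
print.reliability <- function(x, ...) {
  cat(sprintf("inter-rater reliability over %d cells\n", x$n_cells))
  cat(sprintf("  Cohen's kappa = %.3f (Z = %.2f)\n", x$kappa, x$z))
  cat(sprintf("  disagreements = %d; Pearson rho of scores = %.3f\n",
              x$n_disagreements, x$pearson_rho))
  invisible(x)
}
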