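## Model-adequacy diagnostics: pairwise local-dependence chi-squares,
## summed-score (rest-score) item fit, the information/precision grid and
## the TCC monotonicity check.

## collapse a 2-way expected/observed table until every expected cell
## reaches `min_expected`; merges the adjacent row/column whose smallest
## expected cell is worst.  Returns collapsed O, E and the merge maps.
collapse_table <- function(O, E, min_expected = 1) {
  merge_adjacent <- function(M, i, margin) {
    if (margin == 1L) {
      j <- if (i == nrow(M)) i - 1L else i + 1L
      M[j, ] <- M[j, ] + M[i, ]
      M[-i, , drop = FALSE]
    } else {
      j <- if (i == ncol(M)) i - 1L else i + 1L
      M[, j] <- M[, j] + M[, i]
      M[, -i, drop = FALSE]
    }
  }
  repeat {
    if (all(E >= min_expected)) break
    if (nrow(E) <= 2L && ncol(E) <= 2L) break
    worst <- which(E == min(E), arr.ind = TRUE)[1, ]
    row_min <- min(E[worst[1], ])
    ## prefer collapsing the longer dimension
    do_row <- (nrow(E) > 2L) &&
      (ncol(E) <= 2L || nrow(E) >= ncol(E) || row_min < min(E[, worst[2]]))
    if (do_row) {
      O <- merge_adjacent(O, worst[1], 1L); E <- merge_adjacent(E, worst[1], 1L)
    } else {
      O <- merge_adjacent(O, worst[2], 2L); E <- merge_adjacent(E, worst[2], 2L)
    }
  }
  list(O = O, E = E)
}

#' Pairwise local-dependence statistics
#'
#' For every item pair, compares the observed two-way response table with
#' the model-expected table (quadrature integral of the product of the two
#' items' category probabilities over the prior) by a Pearson chi-square on
#' cells collapsed to a minimum expected count.  Both the raw chi-square and
#' its standardized form `(chi2 - df) / sqrt(2 df)` are reported; flagging
#' uses the standardized value, whose null distribution is centred at zero
#' regardless of table size - that is the scale on which the conventional
#' "less than 10" screening rule operates (the raw chi-square has null mean
#' equal to its df, about 16 for two five-category items, so the rule would
#' reject perfect data if applied raw).
#'
#' @param data A [response_matrix()].
#' @param fit A converged `grm_fit` on the same data.
#' @param grid A [theta_grid()].
#' @param threshold Flagging threshold on the standardized statistic;
#'   default 10.
#' @param min_expected Collapsing floor for expected cells.
#' @return A list of class `ld_matrix`: `chi2` and `standardized` (J x J
#'   symmetric matrices, NA diagonal), `df`, `flagged` (logical matrix),
#'   `threshold`.  Pairs whose table cannot be collapsed to computable form
#'   are NA and reported in `not_computable`.
#' @export
ld_chi2 <- function(data, fit, grid = theta_grid(), threshold = 10,
                    min_expected = 1) {
  stopifnot(inherits(data, "response_matrix"), inherits(fit, "grm_fit"))
  if (!fit$converged)
    warning("fit is not converged; local-dependence statistics may be unstable")
  grid <- as_grid(grid)
  J <- ncol(data$responses)
  items <- fit$bank$items
  plist <- lapply(items, function(it) category_probs(it, grid$nodes))
  chi2 <- std <- dfm <- matrix(NA_real_, J, J,
                               dimnames = list(data$item_labels, data$item_labels))
  nc <- character(0)
  for (j in seq_len(J - 1L)) for (l in (j + 1L):J) {
    ok <- !is.na(data$responses[, j]) & !is.na(data$responses[, l])
    n <- sum(ok)
    if (n == 0L) { nc <- c(nc, sprintf("%s:%s", data$item_labels[j], data$item_labels[l])); next }
    O <- table(factor(data$responses[ok, j], levels = 0:(items[[j]]$K - 1L)),
               factor(data$responses[ok, l], levels = 0:(items[[l]]$K - 1L)))
    O <- unclass(O)
    E <- n * plist[[j]] %*% (grid$weights * t(plist[[l]]))
    cl <- collapse_table(O, E, min_expected)
    if (any(cl$E <= 0) || length(cl$E) < 4L) {
      nc <- c(nc, sprintf("%s:%s", data$item_labels[j], data$item_labels[l]))
      next
    }
    x2 <- sum((cl$O - cl$E)^2 / cl$E)
    df <- (nrow(cl$E) - 1L) * (ncol(cl$E) - 1L)
    chi2[j, l] <- chi2[l, j] <- x2
    dfm[j, l] <- dfm[l, j] <- df
    std[j, l] <- std[l, j] <- (x2 - df) / sqrt(2 * df)
  }
  structure(list(chi2 = chi2, standardized = std, df = dfm,
                 flagged = !is.na(std) & std > threshold,
                 threshold = threshold, not_computable = nc),
            class = "ld_matrix")
}

#' @export
print.ld_matrix <- function(x, ...) {
  cat("<ld_matrix> pairwise local dependence (standardized chi-square)\n")
  print(round(x$standardized, 2))
  nf <- sum(x$flagged, na.rm = TRUE) / 2
  cat(sprintf("%d pair(s) above threshold %.1f\n", nf, x$threshold))
  invisible(x)
}

#' Summed-score item-fit statistics
#'
#' Rest-score based item fit: for each item, respondents are grouped by
#' their summed score on the remaining items, observed category frequencies
#' are compared with model-expected frequencies (Lord-Wingersky likelihood
#' of the rest score, integrated over the prior), and a Pearson chi-square
#' is formed after collapsing adjacent rest-score groups (then categories)
#' until every expected count reaches `min_expected`.  Degrees of freedom
#' are the collapsed cell count minus the number of rest-score groups minus
#' the item's free parameters, floored at 1.
#'
#' @inheritParams ld_chi2
#' @param min_expected Minimum expected count after collapsing; default 1.
#' @return A data frame of class `item_fit`: `item`, `s_chi2`, `df`, `p`,
#'   `n_groups` (rest-score groups after collapsing), `n_cells`.
#' @export
s_chi2 <- function(data, fit, grid = theta_grid(), min_expected = 1) {
  stopifnot(inherits(data, "response_matrix"), inherits(fit, "grm_fit"))
  if (!fit$converged)
    warning("fit is not converged; item-fit statistics may be unstable")
  grid <- as_grid(grid)
  J <- ncol(data$responses)
  items <- fit$bank$items
  complete <- rowSums(is.na(data$responses)) == 0L
  resp <- data$responses[complete, , drop = FALSE]
  if (nrow(resp) < 2L)
    stop("item fit needs at least two complete response patterns", call. = FALSE)
  out <- lapply(seq_len(J), function(j) {
    it <- items[[j]]
    x <- resp[, j]
    if (length(unique(x)) < 2L)
      stop(sprintf("item %s has fewer than 2 populated categories",
                   it$label), call. = FALSE)
    rest_bank <- item_bank(items[-j])
    r <- rowSums(resp[, -j, drop = FALSE])
    Smax_r <- max_score(rest_bank)
    O <- unclass(table(factor(r, levels = 0:Smax_r),
                       factor(x, levels = 0:(it$K - 1L))))
    Srest <- score_likelihoods(rest_bank, grid$nodes)     # (Smax_r+1) x Q
    pj <- category_probs(it, grid$nodes)                  # K x Q
    denom <- as.vector(Srest %*% grid$weights)
    keep <- denom > 0 & rowSums(O) >= 0
    Econd <- (Srest %*% (grid$weights * t(pj))) / denom   # P(x=k | rest=r)
    E <- Econd * rowSums(O)
    nz <- rowSums(O) > 0
    cl <- collapse_table(O[nz, , drop = FALSE], E[nz, , drop = FALSE],
                         min_expected)
    x2 <- sum((cl$O - cl$E)^2 / cl$E)
    n_cells <- length(cl$E)
    n_groups <- nrow(cl$E)
    df <- max(n_cells - n_groups - it$K, 1L)
    data.frame(item = it$label, s_chi2 = x2, df = df,
               p = stats::pchisq(x2, df, lower.tail = FALSE),
               n_groups = n_groups, n_cells = n_cells,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  class(out) <- c("item_fit", "data.frame")
  out
}

#' Information/precision grid
#'
#' Item informations on a theta grid plus the test-information and expected
#' standard-error rows - the standard tabular view of scale precision
#' across the latent-trait range.
#'
#' @param bank An [item_bank()].
#' @param thetas Report grid; default -2.8 to 2.8 by 0.4.
#' @param prior_information Added to the item sum; default 1.0 (N(0,1)
#'   population prior).
#' @return A data frame: one row per item plus `test_information` and
#'   `expected_se` rows; one column per theta value.
#' @examples
#' info_table(bsas_bank())
#' @export
info_table <- function(bank, thetas = seq(-2.8, 2.8, by = 0.4),
                       prior_information = 1.0) {
  stopifnot(inherits(bank, "item_bank"))
  M <- t(vapply(bank$items, item_information, numeric(length(thetas)),
                theta = thetas))
  ti <- colSums(M) + prior_information
  out <- rbind(M, test_information = ti, expected_se = 1 / sqrt(ti))
  colnames(out) <- sprintf("theta_%g", thetas)
  as.data.frame(out)
}

#' Monotonicity of the test characteristic curve
#'
#' Passes when the model-expected summed score strictly increases over the
#' theta grid - the basic sanity property of a calibrated scale.
#'
#' @param bank An [item_bank()].
#' @param thetas Theta grid; default -2.8 to 2.8 by 0.4.
#' @param tol Minimum increase per grid step counted as increasing; an
#'   essentially flat curve (slopes near zero) fails.
#' @return A list: `pass` (logical), `tcc` (data frame theta/expected
#'   score).
#' @export
monotonicity_check <- function(bank, thetas = seq(-2.8, 2.8, by = 0.4),
                               tol = 1e-6) {
  stopifnot(inherits(bank, "item_bank"))
  tcc <- expected_score_curve(bank, thetas)
  list(pass = all(diff(tcc) > tol),
       tcc = data.frame(theta = thetas, expected_score = tcc))
}
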