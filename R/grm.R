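## Graded response model mathematics (Samejima).
##
## An item with K ordered categories (coded 0..K-1) has K-1 cumulative
## boundary curves P*_k(theta) = logistic(slope * (theta - b_k)); category
## probabilities are successive differences.  P*_0 = 1 and P*_K = 0 are
## exact constants, never evaluated through the logistic.

#' Cumulative boundary probability
#'
#' Probability of responding in category `k` or above,
#' `P*_k(theta) = 1 / (1 + exp(-slope (theta - b_k)))`, for
#' `k` in `1 .. K-1`.
#'
#' @param item An [item_params()] object.
#' @param k Boundary index, integer in `1 .. K-1`.
#' @param theta Latent-trait value(s).
#' @return Probabilities in (0, 1), same length as `theta`.
#' @export
boundary_prob <- function(item, k, theta) {
  stopifnot(inherits(item, "item_params"))
  if (length(k) != 1L || k < 1L || k > item$K - 1L || k != round(k))
    stop(sprintf("boundary index k must be an integer in 1..%d", item$K - 1L),
         call. = FALSE)
  stats::plogis(item$slope * (theta - item$thresholds[k]))
}

## All boundary curves at once, including the constant P*_0 = 1 and
## P*_K = 0 rows: (K+1) x length(theta) matrix.
boundary_matrix <- function(slope, thresholds, theta) {
  nq <- length(theta)
  ps <- stats::plogis(slope * outer(-thresholds, theta, `+`))
  rbind(rep(1, nq), ps, rep(0, nq))
}

#' Category response probabilities
#'
#' The probability of each response category `0 .. K-1` at `theta`:
#' `P_k = P*_k - P*_(k+1)`.
#'
#' @inheritParams boundary_prob
#' @return For scalar `theta`, a numeric vector of length `K` summing to 1;
#'   for vector `theta`, a `K x length(theta)` matrix.
#' @examples
#' it <- item_params("i", 1.55, c(-1.32, -0.11, 0.56, 1.83))
#' category_probs(it, 0)
#' @export
category_probs <- function(item, theta) {
  stopifnot(inherits(item, "item_params"))
  pm <- boundary_matrix(item$slope, item$thresholds, theta)
  out <- pm[-nrow(pm), , drop = FALSE] - pm[-1, , drop = FALSE]
  rownames(out) <- paste0("cat", seq_len(item$K) - 1L)
  if (length(theta) == 1L) drop(out) else out
}

#' Item information function
#'
#' Samejima's information for a graded item,
#' `I(theta) = slope^2 * sum_k (W_k - W_(k+1))^2 / P_k` with
#' `W_k = P*_k (1 - P*_k)` (and `W_0 = W_K = 0`).
#'
#' @inheritParams boundary_prob
#' @return Nonnegative information value(s), same length as `theta`.
#' @examples
#' it <- item_params("salience", 1.55, c(-1.32, -0.11, 0.56, 1.83))
#' item_information(it, 0)   # about 0.74
#' @export
item_information <- function(item, theta) {
  stopifnot(inherits(item, "item_params"))
  pm <- boundary_matrix(item$slope, item$thresholds, theta)
  W <- pm * (1 - pm)
  P <- pm[-nrow(pm), , drop = FALSE] - pm[-1, , drop = FALSE]
  num <- (W[-nrow(W), , drop = FALSE] - W[-1, , drop = FALSE])^2
  item$slope^2 * colSums(num / P)
}

#' Test information and conditional standard error
#'
#' Test information is the sum of item informations plus the information
#' contributed by the population prior (1.0 for a standard-normal latent
#' distribution); the conditional standard error of measurement is its
#' reciprocal square root.
#'
#' @param bank An [item_bank()].
#' @param theta Latent-trait value(s).
#' @param prior_information Information added by the prior; default 1.0.
#' @return `test_information`: values `>= prior_information`.
#' @examples
#' expected_sem(test_information(bsas_bank(), 0))  # about 0.28
#' @export
test_information <- function(bank, theta, prior_information = 1.0) {
  stopifnot(inherits(bank, "item_bank"), prior_information >= 0)
  infos <- vapply(bank$items, item_information, numeric(length(theta)),
                  theta = theta)
  if (length(theta) == 1L) sum(infos) + prior_information
  else rowSums(infos) + prior_information
}

#' @rdname test_information
#' @param test_info Positive test-information value(s).
#' @export
expected_sem <- function(test_info) {
  if (any(!is.finite(test_info)) || any(test_info <= 0))
    stop("test information must be positive and finite", call. = FALSE)
  1 / sqrt(test_info)
}

#' Slope-intercept parameterization
#'
#' The same boundary logistic written as `P*_k = logistic(slope * theta + c_k)`
#' with intercepts `c_k = -slope * b_k`; `to_intercepts` and
#' `from_intercepts` convert between the two forms (they round-trip exactly).
#'
#' @param item An [item_params()] object.
#' @return `to_intercepts`: numeric vector of `K - 1` strictly decreasing
#'   intercepts.
#' @examples
#' to_intercepts(bsas_bank()$items[[1]])[1]  # 1.55 * 1.32 = 2.05
#' @export
to_intercepts <- function(item) {
  stopifnot(inherits(item, "item_params"))
  -item$slope * item$thresholds
}

#' @rdname to_intercepts
#' @param label,component Passed to [item_params()].
#' @param slope Positive slope.
#' @param intercepts Strictly decreasing intercepts `c_k`.
#' @export
from_intercepts <- function(label, slope, intercepts, component = NA_character_) {
  item_params(label, slope, -intercepts / slope, component = component)
}

#' Test characteristic curve (expected summed score)
#'
#' Model-expected summed score `sum_j sum_k k P_jk(theta)` as a function of
#' theta; strictly increasing whenever all slopes are positive, which is the
#' monotonicity property checked by [monotonicity_check()].
#'
#' @param bank An [item_bank()].
#' @param thetas Numeric vector of latent-trait values.
#' @return Numeric vector of expected scores in `[0, max_score(bank)]`.
#' @export
expected_score_curve <- function(bank, thetas) {
  stopifnot(inherits(bank, "item_bank"))
  per_item <- vapply(bank$items, function(it) {
    p <- category_probs(it, thetas)
    if (is.null(dim(p))) sum((seq_len(it$K) - 1L) * p)
    else colSums(p * (seq_len(it$K) - 1L))
  }, numeric(length(thetas)))
  if (length(thetas) == 1L) sum(per_item) else rowSums(per_item)
}

#' Long-format curve table for plotting or export
#'
#' Evaluates the standard IRT curves on a theta grid and stacks them in long
#' format (`theta`, `item`, `quantity`, `value`): category response curves
#' (`icc`, one series per category), item information (`iif`), test
#' characteristic curve (`tcc`), test information (`tif`) and conditional
#' standard error (`se`).
#'
#' @param bank An [item_bank()].
#' @param thetas Theta values; default is the reporting grid -2.8..2.8 by 0.4.
#' @param quantities Subset of `c("icc", "iif", "tcc", "tif", "se")`.
#' @param prior_information Passed to [test_information()].
#' @return A long data frame with columns `theta`, `item`, `quantity`, `value`.
#' @export
curve_table <- function(bank, thetas = seq(-2.8, 2.8, by = 0.4),
                        quantities = c("icc", "iif", "tcc", "tif", "se"),
                        prior_information = 1.0) {
  stopifnot(inherits(bank, "item_bank"))
  quantities <- match.arg(quantities, several.ok = TRUE)
  out <- list()
  if ("icc" %in% quantities) {
    for (it in bank$items) {
      p <- category_probs(it, thetas)
      if (is.null(dim(p))) p <- matrix(p, ncol = 1)
      for (k in seq_len(it$K)) {
        out[[length(out) + 1L]] <- data.frame(
          theta = thetas, item = it$label,
          quantity = paste0("icc_cat", k - 1L), value = p[k, ])
      }
    }
  }
  if ("iif" %in% quantities) {
    for (it in bank$items)
      out[[length(out) + 1L]] <- data.frame(
        theta = thetas, item = it$label, quantity = "iif",
        value = item_information(it, thetas))
  }
  ti <- test_information(bank, thetas, prior_information)
  if ("tcc" %in% quantities)
    out[[length(out) + 1L]] <- data.frame(
      theta = thetas, item = "test", quantity = "tcc",
      value = expected_score_curve(bank, thetas))
  if ("tif" %in% quantities)
    out[[length(out) + 1L]] <- data.frame(
      theta = thetas, item = "test", quantity = "tif", value = ti)
  if ("se" %in% quantities)
    out[[length(out) + 1L]] <- data.frame(
      theta = thetas, item = "test", quantity = "se", value = expected_sem(ti))
  do.call(rbind, out)
}
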