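## Summed-score machinery: Lord-Wingersky recursion, summed-score EAP
## conversion (SSEAP), SD-band cut-offs and risk classification.

#' Summed-score likelihoods (Lord-Wingersky recursion)
#'
#' Distribution of the summed score given theta, built item by item from the
#' category probabilities by the Lord-Wingersky dynamic program.
#'
#' @param bank An [item_bank()].
#' @param theta Latent-trait value(s).
#' @return For scalar `theta`, a probability vector over scores
#'   `0 .. max_score(bank)` (sums to 1); for vector `theta`, a matrix with
#'   one column per theta value.
#' @export
score_likelihoods <- function(bank, theta) {
  stopifnot(inherits(bank, "item_bank"))
  nq <- length(theta)
  S <- matrix(1, 1, nq)   # P(score = 0 | theta) before any item
  for (it in bank$items) {
    p <- category_probs(it, theta)
    if (is.null(dim(p))) p <- matrix(p, ncol = 1)
    K <- it$K
    new <- matrix(0, nrow(S) + K - 1L, nq)
    for (k in seq_len(K))
      new[seq_len(nrow(S)) + k - 1L, ] <-
        new[seq_len(nrow(S)) + k - 1L, , drop = FALSE] +
        S * rep(p[k, ], each = nrow(S))
    S <- new
  }
  rownames(S) <- paste0("s", seq_len(nrow(S)) - 1L)
  if (nq == 1L) drop(S) else S
}

#' Summed-score to EAP conversion table
#'
#' For every possible summed score `s`, the posterior mean `EAP[theta | s]`
#' and SD of theta under the population prior carried by `grid`, plus the
#' modelled proportion of the population attaining `s` (the prior-weighted
#' marginal score probability).  This is the summed-score EAP (SSEAP)
#' conversion used to map raw screening scores onto the latent severity
#' scale.
#'
#' @param bank An [item_bank()].
#' @param grid A [theta_grid()]; default 49 nodes on \[-6, 6\], N(0, 1).
#' @return A data frame of class `score_table` with columns `summed_score`,
#'   `eap`, `sd`, `modelled_proportion`.
#' @examples
#' tab <- build_score_table(bsas_bank())
#' head(tab)
#' @export
build_score_table <- function(bank, grid = theta_grid()) {
  stopifnot(inherits(bank, "item_bank"))
  grid <- as_grid(grid)
  S <- score_likelihoods(bank, grid$nodes)          # (Smax+1) x Q
  post <- S * rep(grid$weights, each = nrow(S))
  marg <- rowSums(post)
  if (any(marg <= 0))
    stop("some summed scores have zero marginal probability; degenerate bank",
         call. = FALSE)
  eap <- as.vector(post %*% grid$nodes) / marg
  m2 <- as.vector(post %*% grid$nodes^2) / marg
  out <- data.frame(summed_score = seq_len(nrow(S)) - 1L,
                    eap = eap,
                    sd = sqrt(pmax(m2 - eap^2, 0)),
                    modelled_proportion = marg)
  class(out) <- c("score_table", "data.frame")
  ## monotone EAP is guaranteed when slopes are equal and is the normal
  ## state for calibrated banks, but extreme slope heterogeneity on short
  ## scales can break it; record rather than fail
  attr(out, "monotone_eap") <- all(diff(eap) > 0)
  out
}

#' Risk-band cut-offs from a score table
#'
#' The smallest summed score whose EAP meets or exceeds each SD band on the
#' latent scale (prior SD = 1), e.g. bands `c(1, 2)` give the medium- and
#' high-risk raw-score cut-offs.
#'
#' @param table A [build_score_table()] result.
#' @param bands Numeric vector of SD multiples; default `c(1, 2)`.
#' @return A data frame with columns `band` and `score`; `score` is NA (with
#'   attribute `attainable = FALSE`) when no summed score reaches the band.
#' @examples
#' derive_cutoffs(build_score_table(bsas_bank()))
#' @export
derive_cutoffs <- function(table, bands = c(1, 2)) {
  stopifnot(inherits(table, "score_table"))
  score <- vapply(bands, function(bd) {
    hit <- which(table$eap >= bd)
    if (!length(hit)) NA_integer_ else table$summed_score[hit[1]]
  }, integer(1))
  out <- data.frame(band = bands, score = score)
  attr(out, "attainable") <- !is.na(score)
  out
}

#' Pattern-level EAP score
#'
#' Posterior mean and SD of theta for one respondent's response pattern,
#' using only the observed items (the pattern-level analogue of the
#' summed-score EAP; the natural scorer for respondents with missing items).
#'
#' @param bank An [item_bank()].
#' @param responses Integer vector of length `length(bank)`, values
#'   `0 .. K_j - 1` or NA.
#' @param grid A [theta_grid()].
#' @return A list with `eap` and `sd`.
#' @export
pattern_eap <- function(bank, responses, grid = theta_grid()) {
  stopifnot(inherits(bank, "item_bank"),
            length(responses) == length(bank$items))
  grid <- as_grid(grid)
  if (all(is.na(responses)))
    stop("all responses missing; no posterior can be formed", call. = FALSE)
  L <- rep(1, length(grid$nodes))
  for (j in seq_along(bank$items)) {
    if (is.na(responses[j])) next
    p <- category_probs(bank$items[[j]], grid$nodes)
    L <- L * p[responses[j] + 1L, ]
  }
  post <- L * grid$weights
  post <- post / sum(post)
  eap <- sum(post * grid$nodes)
  list(eap = eap, sd = sqrt(max(sum(post * grid$nodes^2) - eap^2, 0)))
}

#' Classify respondents into risk bands
#'
#' Summed scores are cut at the raw-score bounds in `cutoffs` (from
#' [derive_cutoffs()]): below the first band is low risk, at or above the
#' last is high risk.  Respondents with missing items are excluded by
#' default (`policy = "exclude"`); `policy = "pattern_eap"` instead scores
#' them by [pattern_eap()] and applies the bands on the latent scale.
#'
#' @param data A [response_matrix()].
#' @param cutoffs A data frame from [derive_cutoffs()] (columns `band`,
#'   `score`), typically bands `c(1, 2)`.
#' @param policy Missing-data policy: `"exclude"` or `"pattern_eap"`.
#' @param bank,grid Needed only for `policy = "pattern_eap"`.
#' @return A list with `respondents` (id, group, summed score, band),
#'   `summary` (band-by-group counts) and, when at least two groups are
#'   present, `high_risk_test`: a chi-squared test of high-risk status
#'   between the two largest groups.
#' @export
classify <- function(data, cutoffs, policy = c("exclude", "pattern_eap"),
                     bank = NULL, grid = theta_grid()) {
  stopifnot(inherits(data, "response_matrix"))
  policy <- match.arg(policy)
  if (!all(c("band", "score") %in% names(cutoffs)))
    stop("`cutoffs` must have columns `band` and `score`", call. = FALSE)
  cutoffs <- cutoffs[order(cutoffs$band), , drop = FALSE]
  if (anyNA(cutoffs$score))
    stop("unattainable cut-off band supplied to classify()", call. = FALSE)
  labels <- c("low", if (nrow(cutoffs) > 1L) "medium", "high")
  if (nrow(cutoffs) == 1L) labels <- c("low", "high")

  resp <- data$responses
  complete <- rowSums(is.na(resp)) == 0L
  ssc <- rowSums(resp)
  band <- rep(NA_character_, nrow(resp))
  eap <- rep(NA_real_, nrow(resp))

  band_of_score <- function(s) labels[1L + rowSums(outer(s, cutoffs$score, `>=`))]
  band[complete] <- band_of_score(ssc[complete])

  if (policy == "pattern_eap" && any(!complete)) {
    if (is.null(bank))
      stop("`bank` is required for policy = \"pattern_eap\"", call. = FALSE)
    for (i in which(!complete & rowSums(!is.na(resp)) > 0L)) {
      pe <- pattern_eap(bank, resp[i, ], grid)
      eap[i] <- pe$eap
      band[i] <- labels[1L + sum(pe$eap >= cutoffs$band)]
    }
  }

  res <- data.frame(id = seq_len(nrow(resp)),
                    group = if (is.null(data$groups)) NA_character_ else data$groups,
                    summed_score = ifelse(complete, ssc, NA_integer_),
                    eap = eap, band = band,
                    stringsAsFactors = FALSE)
  keep <- !is.na(res$band)
  summary_tab <- table(band = factor(res$band[keep], levels = labels),
                       group = if (is.null(data$groups)) rep("all", sum(keep))
                       else res$group[keep])

  high_test <- NULL
  if (!is.null(data$groups)) {
    big2 <- names(sort(table(res$group[keep]), decreasing = TRUE))[1:2]
    sub <- res[keep & res$group %in% big2, ]
    if (length(unique(sub$group)) == 2L) {
      tab <- table(sub$group, sub$band == "high")
      if (all(dim(tab) == c(2L, 2L))) {
        ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
        high_test <- list(groups = big2, chi2 = unname(ht$statistic),
                          df = unname(ht$parameter), p = ht$p.value)
      }
    }
  }
  list(respondents = res, summary = summary_tab, high_risk_test = high_test)
}

#' Export a score table
#'
#' Delimited text with columns `summed_score`, `eap`, `sd`,
#' `modelled_proportion`.
#'
#' @param table A `score_table`.
#' @param path Output path.
#' @export
write_score_table <- function(table, path) {
  stopifnot(inherits(table, "score_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
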