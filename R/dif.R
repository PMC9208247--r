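## Multi-group graded-response estimation and Wald DIF testing.
##
## Identification follows the anchored-calibration convention: the
## reference group's latent distribution is fixed at N(0, 1), focal-group
## means and SDs are estimated, anchored items share parameters across
## groups, and candidate items get group-specific parameters.  Wald
## statistics use the joint empirical (cross-product) information of all
## free parameters, so the covariance between the two groups' estimates of
## a freed item (induced by the shared anchors and latent parameters) is
## accounted for.

#' Fit the graded response model in several groups
#'
#' @param data A [response_matrix()] with group labels.
#' @param free_items Labels (or indices) of items given group-specific
#'   parameters; all other items are anchored (shared).  Default: none
#'   freed (impact-only model).
#' @param groups Which group labels to include; default the two largest.
#'   Use `groups = "all"` to keep every group.
#' @param reference Reference group label (latent distribution fixed at
#'   N(0, 1)); default the largest included group.
#' @param grid A [theta_grid()] giving the quadrature nodes; focal-group
#'   weights are renormalized normal densities on the same nodes.
#' @param control A [grm_control()].
#' @return An object of class `mg_fit`: per-group banks, latent-parameter
#'   table, log-likelihood, and the joint parameter covariance needed by
#'   [wald_dif()].
#' @export
fit_multigroup <- function(data, free_items = character(0),
                           groups = NULL, reference = NULL,
                           grid = theta_grid(), control = grm_control()) {
  stopifnot(inherits(data, "response_matrix"))
  if (is.null(data$groups))
    stop("`data` has no group labels; multigroup estimation needs them",
         call. = FALSE)
  grid <- as_grid(grid)
  tab <- sort(table(data$groups), decreasing = TRUE)
  if (is.null(groups)) groups <- names(tab)[seq_len(min(2L, length(tab)))]
  else if (identical(groups, "all")) groups <- names(tab)
  groups <- as.character(groups)
  if (length(groups) < 1L || !all(groups %in% names(tab)))
    stop("unknown group label(s) requested", call. = FALSE)
  small <- tab[groups] < 50L
  if (any(small))
    warning(sprintf("group(s) %s have fewer than 50 respondents",
                    paste(groups[small], collapse = ", ")))
  if (is.null(reference)) reference <- groups[which.max(tab[groups])]
  stopifnot(reference %in% groups)
  groups <- c(reference, setdiff(groups, reference))
  G <- length(groups)

  J <- ncol(data$responses); K <- data$n_cat
  labs <- data$item_labels
  if (is.numeric(free_items)) free_items <- labs[free_items]
  if (!all(free_items %in% labs))
    stop("unknown item label(s) in `free_items`", call. = FALSE)
  free <- labs %in% free_items
  if (all(free) && G > 1L)
    stop("all items freed with no anchor; the group scales are not identified",
         call. = FALSE)

  keep <- data$groups %in% groups
  resp_all <- data$responses[keep, , drop = FALSE]
  grp_all <- data$groups[keep]
  gdata <- lapply(groups, function(g) {
    r <- resp_all[grp_all == g, , drop = FALSE]
    cp <- collapse_patterns(response_matrix(r, item_labels = labs, n_cat = K))
    list(pats = cp$patterns, cnt = cp$counts, n = nrow(r), resp = r)
  })
  names(gdata) <- groups

  ## starting values pooled across groups
  a <- matrix(1, J, G, dimnames = list(labs, groups))
  bstart <- lapply(seq_len(J), function(j) start_thresholds(resp_all[, j], K[j]))
  b <- lapply(seq_len(J), function(j) {
    out <- vector("list", G); for (g in seq_len(G)) out[[g]] <- bstart[[j]]; out
  })
  mu <- stats::setNames(rep(0, G), groups)
  sig <- stats::setNames(rep(1, G), groups)

  nodes <- grid$nodes; Q <- length(nodes)
  group_weights <- function() lapply(seq_len(G), function(g) {
    w <- stats::dnorm(nodes, mu[g], sig[g]); w / sum(w)
  })

  converged <- FALSE
  ll_trace <- numeric(0); delta_trace <- numeric(0)
  for (cyc in seq_len(control$max_cycles)) {
    wlist <- group_weights()
    old <- c(a, unlist(b), mu, sig)
    es <- vector("list", G); postw <- vector("list", G)
    ll <- 0
    for (g in seq_len(G)) {
      plist <- item_prob_list(a[, g], lapply(b, `[[`, g), nodes)
      es[[g]] <- estep_patterns(gdata[[g]]$pats, gdata[[g]]$cnt, plist, wlist[[g]])
      postw[[g]] <- es[[g]]$posterior * gdata[[g]]$cnt
      ll <- ll + es[[g]]$loglik
    }
    ll_trace <- c(ll_trace, ll)

    for (j in seq_len(J)) {
      if (!free[j]) {
        nj <- Reduce(`+`, lapply(seq_len(G), function(g)
          expected_counts(gdata[[g]]$pats[, j], postw[[g]], K[j], Q)))
        opt <- stats::optim(par_pack(a[j, 1], b[[j]][[1]]), neg_q_item,
                            neg_q_grad, nj = nj, nodes = nodes, method = "BFGS",
                            control = list(maxit = control$m_iter))
        u <- par_unpack(opt$par)
        a[j, ] <- u$a
        for (g in seq_len(G)) b[[j]][[g]] <- u$b
      } else {
        for (g in seq_len(G)) {
          nj <- expected_counts(gdata[[g]]$pats[, j], postw[[g]], K[j], Q)
          opt <- stats::optim(par_pack(a[j, g], b[[j]][[g]]), neg_q_item,
                              neg_q_grad, nj = nj, nodes = nodes, method = "BFGS",
                              control = list(maxit = control$m_iter))
          u <- par_unpack(opt$par)
          a[j, g] <- u$a; b[[j]][[g]] <- u$b
        }
      }
    }
    ## latent distribution of focal groups from posterior moments
    for (g in seq_len(G)[-1]) {
      tot <- colSums(postw[[g]])
      n_g <- sum(tot)
      m1 <- sum(tot * nodes) / n_g
      v <- sum(tot * nodes^2) / n_g - m1^2
      mu[g] <- m1; sig[g] <- sqrt(max(v, 1e-4))
    }
    delta <- max(abs(c(a, unlist(b), mu, sig) - old))
    delta_trace <- c(delta_trace, delta)
    if (delta < control$tol) { converged <- TRUE; break }
  }

  wlist <- group_weights()
  ll <- 0
  for (g in seq_len(G)) {
    plist <- item_prob_list(a[, g], lapply(b, `[[`, g), nodes)
    ll <- ll + estep_patterns(gdata[[g]]$pats, gdata[[g]]$cnt, plist,
                              wlist[[g]])$loglik
  }
  n_params <- sum(ifelse(free, G * K, K)) + 2L * (G - 1L)
  N <- sum(vapply(gdata, `[[`, numeric(1), "n"))

  banks <- lapply(seq_len(G), function(g)
    item_bank(lapply(seq_len(J), function(j)
      item_params(labs[j], a[j, g], b[[j]][[g]]))))
  names(banks) <- groups

  fit <- structure(list(
    banks = banks, groups = groups, reference = reference,
    latent = data.frame(group = groups, mean = unname(mu), sd = unname(sig)),
    free_items = labs[free], anchors = labs[!free],
    loglik = ll, n_params = n_params, n_used = N,
    converged = converged, n_cycles = length(delta_trace),
    trace = delta_trace, loglik_trace = ll_trace,
    grid = grid, K = K, item_labels = labs),
    class = "mg_fit")

  if (control$se) {
    se <- tryCatch(
      mg_opg(gdata, a, b, K, free, mu, sig, nodes, wlist, groups),
      error = function(e) {
        warning("joint information unavailable: ", conditionMessage(e))
        NULL
      })
    fit$vcov <- se$vcov
    fit$par_names <- se$par_names
  }
  fit
}

## joint OPG information across all free parameters of a multigroup fit
mg_opg <- function(gdata, a, b, K, free, mu, sig, nodes, wlist, groups) {
  G <- length(groups); J <- nrow(a); Q <- length(nodes)
  par_names <- character(0)
  for (j in seq_len(J)) {
    if (!free[j]) par_names <- c(par_names,
      sprintf("%s:a", rownames(a)[j]), sprintf("%s:b%d", rownames(a)[j], seq_len(K[j] - 1L)))
    else for (g in seq_len(G)) par_names <- c(par_names,
      sprintf("%s@%s:a", rownames(a)[j], groups[g]),
      sprintf("%s@%s:b%d", rownames(a)[j], groups[g], seq_len(K[j] - 1L)))
  }
  for (g in seq_len(G)[-1])
    par_names <- c(par_names, sprintf("latent@%s:mean", groups[g]),
                   sprintf("latent@%s:sd", groups[g]))
  P <- length(par_names)
  info <- matrix(0, P, P, dimnames = list(par_names, par_names))
  for (g in seq_len(G)) {
    pats <- gdata[[g]]$pats; cnt <- gdata[[g]]$cnt
    plist <- item_prob_list(a[, g], lapply(b, `[[`, g), nodes)
    es <- estep_patterns(pats, cnt, plist, wlist[[g]])
    post <- es$posterior
    npat <- nrow(pats)
    S <- matrix(0, npat, P, dimnames = list(NULL, par_names))
    for (j in seq_len(J)) {
      sm <- item_score_mats(a[j, g], b[[j]][[g]], nodes)
      idx <- pats[, j]; obs <- !is.na(idx)
      pick <- function(gmat) {
        v <- numeric(npat)
        if (any(obs))
          v[obs] <- rowSums(post[obs, , drop = FALSE] *
                              gmat[idx[obs] + 1L, , drop = FALSE])
        v
      }
      pre <- if (!free[j]) sprintf("%s:", rownames(a)[j])
      else sprintf("%s@%s:", rownames(a)[j], groups[g])
      S[, paste0(pre, "a")] <- pick(sm$slope)
      for (m in seq_len(K[j] - 1L))
        S[, paste0(pre, "b", m)] <- pick(sm[[paste0("b", m)]])
    }
    if (g > 1L) {
      z <- (nodes - mu[g]) / sig[g]
      w <- wlist[[g]]
      dmu <- (z - sum(w * z)) / sig[g]
      dsg <- (z^2 - sum(w * z^2)) / sig[g]
      S[, sprintf("latent@%s:mean", groups[g])] <- as.vector(post %*% dmu)
      S[, sprintf("latent@%s:sd", groups[g])] <- as.vector(post %*% dsg)
    }
    info <- info + crossprod(S * sqrt(cnt))
  }
  V <- tryCatch(solve(info), error = function(e)
    stop("singular joint information; consider collapsing categories or ",
         "larger groups", call. = FALSE))
  list(vcov = V, par_names = par_names)
}

#' @export
print.mg_fit <- function(x, ...) {
  cat(sprintf("<mg_fit> %d groups (%s; reference %s), N = %d\n",
              length(x$groups), paste(x$groups, collapse = ", "),
              x$reference, x$n_used))
  cat(sprintf("  freed: %s\n",
              if (length(x$free_items)) paste(x$free_items, collapse = ", ")
              else "none (all anchored)"))
  print(x$latent, digits = 3)
  cat(sprintf("  loglik %.2f, %d params, %s in %d cycles\n", x$loglik,
              x$n_params, if (x$converged) "converged" else "NOT converged",
              x$n_cycles))
  invisible(x)
}

#' Wald DIF test for one freed item
#'
#' Tests the between-group difference of a freed item's parameters with
#' three quadratic forms: the total chi-square on all `K` contrasts (slope
#' plus `K - 1` thresholds), the slope-only chi-square (df 1), and the
#' threshold chi-square with the slope difference partialled out via the
#' conditional covariance (df `K - 1`).  Degrees of freedom add up:
#' `df_total = df_a + df_cja`.
#'
#' @param fit An `mg_fit` with the item freed and `vcov` available.
#' @param item Item label (or index).
#' @param pair Length-2 character: which two groups to contrast; default
#'   the reference and the first focal group.
#' @return A one-row data frame: `item`, `chi2_total`, `df_total`,
#'   `p_total`, `chi2_a`, `df_a`, `p_a`, `chi2_cja`, `df_cja`, `p_cja`,
#'   plus the per-group slope and threshold estimates as attributes
#'   `estimates`.
#' @export
wald_dif <- function(fit, item, pair = NULL) {
  stopifnot(inherits(fit, "mg_fit"))
  if (is.numeric(item)) item <- fit$item_labels[item]
  if (!item %in% fit$free_items)
    stop(sprintf("item %s is not freed in this fit", item), call. = FALSE)
  if (is.null(fit$vcov))
    stop("fit carries no parameter covariance; refit with se = TRUE",
         call. = FALSE)
  if (is.null(pair)) pair <- fit$groups[1:2]
  stopifnot(length(pair) == 2L, all(pair %in% fit$groups))
  Kj <- fit$K[match(item, fit$item_labels)]
  nm <- function(g) c(sprintf("%s@%s:a", item, g),
                      sprintf("%s@%s:b%d", item, g, seq_len(Kj - 1L)))
  n1 <- nm(pair[1]); n2 <- nm(pair[2])
  V <- fit$vcov
  th <- function(g) {
    it <- fit$banks[[g]]$items[[item]]
    c(it$slope, it$thresholds)
  }
  d <- th(pair[2]) - th(pair[1])
  Vd <- V[n2, n2] + V[n1, n1] - V[n2, n1] - V[n1, n2]
  qform <- function(x, S) {
    sol <- tryCatch(solve(S, x), error = function(e)
      stop("singular contrast covariance; categories may need collapsing",
           call. = FALSE))
    drop(crossprod(x, sol))
  }
  chi2_total <- qform(d, Vd)
  chi2_a <- d[1]^2 / Vd[1, 1]
  ## thresholds with the slope difference partialled out
  Vaa <- Vd[1, 1]; Vca <- Vd[-1, 1, drop = FALSE]; Vcc <- Vd[-1, -1]
  d_cja <- d[-1] - Vca %*% (d[1] / Vaa)
  V_cja <- Vcc - tcrossprod(Vca) / Vaa
  chi2_cja <- qform(drop(d_cja), V_cja)
  out <- data.frame(
    item = item,
    chi2_total = chi2_total, df_total = Kj,
    p_total = stats::pchisq(chi2_total, Kj, lower.tail = FALSE),
    chi2_a = chi2_a, df_a = 1L,
    p_a = stats::pchisq(chi2_a, 1L, lower.tail = FALSE),
    chi2_cja = chi2_cja, df_cja = Kj - 1L,
    p_cja = stats::pchisq(chi2_cja, Kj - 1L, lower.tail = FALSE),
    stringsAsFactors = FALSE)
  attr(out, "estimates") <- stats::setNames(
    list(th(pair[1]), th(pair[2])), pair)
  out
}

#' Two-stage anchored DIF sweep
#'
#' Stage 1 tests each item in turn with all other items anchored.  Items
#' non-significant at `alpha` form the anchor set; stage 2 frees all
#' remaining candidates simultaneously against that anchor set and retests
#' them.  The final report carries stage-2 statistics for candidates and
#' stage-1 statistics for anchors - the standard guard against anchor
#' contamination inflating type-I error.
#'
#' @param data A [response_matrix()] with groups.
#' @param grid A [theta_grid()].
#' @param alpha Significance level for anchoring decisions; default 0.05.
#' @param adjust P-value adjustment across items at stage 1: `"none"`
#'   (default) or `"BH"`.
#' @param groups,reference Passed to [fit_multigroup()].
#' @param control A [grm_control()].
#' @return A data frame of class `dif_report` (one row per item, Wald
#'   decomposition columns plus `stage` and `anchor`), with attributes
#'   `anchors` and `alpha`.
#' @export
dif_sweep <- function(data, grid = theta_grid(), alpha = 0.05,
                      adjust = c("none", "BH"), groups = NULL,
                      reference = NULL, control = grm_control()) {
  adjust <- match.arg(adjust)
  labs <- data$item_labels
  stage1 <- lapply(labs, function(it) {
    f <- fit_multigroup(data, free_items = it, groups = groups,
                        reference = reference, grid = grid, control = control)
    wald_dif(f, it)
  })
  stage1 <- do.call(rbind, stage1)
  p1 <- if (adjust == "BH") stats::p.adjust(stage1$p_total, "BH")
  else stage1$p_total
  anchors <- labs[p1 >= alpha]
  candidates <- setdiff(labs, anchors)

  report <- stage1
  report$stage <- 1L
  if (!length(anchors)) {
    warning("no invariant items found at stage 1; returning stage-1 ",
            "statistics without an anchored retest")
  } else if (length(candidates)) {
    f2 <- fit_multigroup(data, free_items = candidates, groups = groups,
                         reference = reference, grid = grid, control = control)
    for (it in candidates) {
      row <- wald_dif(f2, it)
      row$stage <- 2L
      report[report$item == it, names(row)] <- row
    }
  }
  report$anchor <- report$item %in% anchors
  report$flagged <- !report$anchor & report$p_total < alpha
  class(report) <- c("dif_report", "data.frame")
  attr(report, "anchors") <- anchors
  attr(report, "alpha") <- alpha
  report
}

#' Export a DIF report
#'
#' Delimited table (item, total/slope/threshold chi-squares with dfs and
#' p-values) plus a JSON sidecar with anchor set and settings when `json`
#' is given.
#'
#' @param report A `dif_report`.
#' @param path CSV output path.
#' @param json Optional JSON output path.
#' @export
write_dif_report <- function(report, path, json = NULL) {
  stopifnot(inherits(report, "dif_report"))
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(
      list(anchors = attr(report, "anchors"),
           alpha = attr(report, "alpha"),
           report = as.data.frame(report)),
      json, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
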