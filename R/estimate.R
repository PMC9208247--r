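## Bock-Aitkin marginal maximum likelihood EM for the graded response model.
##
## The E-step computes, for every distinct response pattern, the posterior
## weight of each quadrature node given the current item parameters; the
## M-step maximizes each item's expected complete-data log-likelihood by
## quasi-Newton on an unconstrained reparameterization (log slope; first
## threshold plus log spacings), which enforces slope positivity and
## threshold ordering without explicit constraints.

#' Estimation settings
#'
#' @param tol Convergence tolerance: largest absolute parameter change
#'   between EM cycles.
#' @param max_cycles Cycle cap; hitting it flags the fit `converged = FALSE`.
#' @param se Compute standard errors (empirical cross-product information)?
#' @param m_iter Quasi-Newton iterations per item per M-step (a partial
#'   M-step; the EM objective still increases every cycle).
#' @return A list of class `grm_control`.
#' @export
grm_control <- function(tol = 1e-4, max_cycles = 500L, se = TRUE,
                        m_iter = 25L) {
  stopifnot(tol > 0, max_cycles >= 1L)
  structure(list(tol = tol, max_cycles = as.integer(max_cycles),
                 se = isTRUE(se), m_iter = as.integer(m_iter)),
            class = "grm_control")
}

## category-probability matrices (K_j x Q) for every item at the nodes
item_prob_list <- function(a, b, nodes, floor = 1e-300) {
  lapply(seq_along(a), function(j) {
    pm <- boundary_matrix(a[j], b[[j]], nodes)
    pmax(pm[-nrow(pm), , drop = FALSE] - pm[-1, , drop = FALSE], floor)
  })
}

## E-step over unique patterns: pattern-by-node likelihood, marginal,
## posterior weights and log-likelihood
estep_patterns <- function(pats, cnt, plist, w) {
  npat <- nrow(pats); Q <- length(w)
  L <- matrix(1, npat, Q)
  for (j in seq_len(ncol(pats))) {
    idx <- pats[, j]
    obs <- !is.na(idx)
    if (any(obs))
      L[obs, ] <- L[obs, ] * plist[[j]][idx[obs] + 1L, , drop = FALSE]
  }
  m <- as.vector(L %*% w)
  post <- L * rep(w, each = npat) / m
  list(L = L, marginal = m, posterior = post,
       loglik = sum(cnt * log(m)))
}

## expected category-by-node count table for one item (K x Q)
expected_counts <- function(pats_j, post_w, K, Q) {
  obs <- !is.na(pats_j)
  nj <- matrix(0, K, Q)
  if (any(obs)) {
    tmp <- rowsum(post_w[obs, , drop = FALSE], pats_j[obs])
    nj[as.integer(rownames(tmp)) + 1L, ] <- tmp
  }
  nj
}

## reparameterization helpers: par = (log a, b1, log diffs)
par_pack <- function(a, b) c(log(a), b[1], log(diff(b)))
par_unpack <- function(p) {
  a <- exp(p[1])
  b <- cumsum(c(p[2], exp(p[-(1:2)])))
  list(a = a, b = b)
}

neg_q_item <- function(p, nj, nodes, fixed_a = NULL) {
  if (is.null(fixed_a)) {
    u <- par_unpack(p); a <- u$a; b <- u$b
  } else {
    a <- fixed_a; b <- cumsum(c(p[1], exp(p[-1])))
  }
  pm <- boundary_matrix(a, b, nodes)
  P <- pmax(pm[-nrow(pm), , drop = FALSE] - pm[-1, , drop = FALSE], 1e-300)
  -sum(nj * log(P))
}

## analytic gradient of neg_q_item on the reparameterized space
neg_q_grad <- function(p, nj, nodes, fixed_a = NULL) {
  if (is.null(fixed_a)) {
    u <- par_unpack(p); a <- u$a; b <- u$b
  } else {
    a <- fixed_a; b <- cumsum(c(p[1], exp(p[-1])))
  }
  Km1 <- length(b)
  pm <- boundary_matrix(a, b, nodes)            # (K+1) x Q
  W <- pm * (1 - pm)
  P <- pmax(pm[-nrow(pm), , drop = FALSE] - pm[-1, , drop = FALSE], 1e-300)
  R <- nj / P                                   # K x Q
  ## d(-Q)/da: dP*_k/da = W_k (theta - b_k) on interior rows
  dstar_a <- W * rbind(0, outer(-b, nodes, `+`), 0)
  g_a <- -sum((dstar_a[-nrow(dstar_a), , drop = FALSE] -
                 dstar_a[-1, , drop = FALSE]) * R)
  ## d(-Q)/db_m: categories m-1 and m (0-based) touch boundary m
  ## category m-1 (0-based) gains +a W_m, category m loses it
  g_b <- vapply(seq_len(Km1), function(m) {
    aW <- a * W[m + 1L, ]
    -sum(aW * R[m, ] - aW * R[m + 1L, ])
  }, numeric(1))
  if (is.null(fixed_a)) {
    ## chain rule to (log a, b1, log diffs)
    gl <- numeric(1L + Km1)
    gl[1] <- g_a * a
    gl[2] <- sum(g_b)
    if (Km1 > 1L)
      gl[3:(Km1 + 1L)] <- vapply(seq_len(Km1 - 1L), function(i)
        exp(p[2L + i]) * sum(g_b[(i + 1L):Km1]), numeric(1))
    gl
  } else {
    gl <- numeric(Km1)
    gl[1] <- sum(g_b)
    if (Km1 > 1L)
      gl[2:Km1] <- vapply(seq_len(Km1 - 1L), function(i)
        exp(p[1L + i]) * sum(g_b[(i + 1L):Km1]), numeric(1))
    gl
  }
}

## starting thresholds from inverse-logit transforms of cumulative
## observed category proportions (slope 1 start)
start_thresholds <- function(x, K) {
  p_ge <- vapply(seq_len(K - 1L), function(k) mean(x >= k, na.rm = TRUE),
                 numeric(1))
  p_ge <- pmin(pmax(p_ge, 0.005), 0.995)
  b <- -stats::qlogis(p_ge)
  ## enforce strict ordering for degenerate starts
  for (k in seq_along(b)[-1])
    if (b[k] <= b[k - 1L]) b[k] <- b[k - 1L] + 0.05
  b
}

em_engine <- function(data, grid, constraint = c("free", "common", "fixed"),
                      fixed_slope = 1.0, control = grm_control()) {
  constraint <- match.arg(constraint)
  stopifnot(inherits(data, "response_matrix"))
  grid <- as_grid(grid)
  nodes <- grid$nodes; w <- grid$weights; Q <- length(nodes)

  resp <- data$responses
  all_na <- rowSums(!is.na(resp)) == 0L
  if (any(all_na)) {
    warning(sprintf("dropping %d respondent(s) with no observed responses",
                    sum(all_na)))
    resp <- resp[!all_na, , drop = FALSE]
  }
  N <- nrow(resp); J <- ncol(resp); K <- data$n_cat
  if (N < 15L * J)
    warning(sprintf("only %d respondents for %d items; below the 15-per-item rule",
                    N, J))
  for (j in seq_len(J)) {
    ncats <- length(unique(resp[!is.na(resp[, j]), j]))
    if (ncats < 2L)
      stop(sprintf("item %s has fewer than 2 observed categories; cannot be estimated",
                   data$item_labels[j]), call. = FALSE)
  }

  cp <- collapse_patterns(response_matrix(resp, item_labels = data$item_labels,
                                          n_cat = K))
  pats <- cp$patterns; cnt <- cp$counts

  a <- if (constraint == "fixed") rep(fixed_slope, J) else rep(1, J)
  b <- lapply(seq_len(J), function(j) start_thresholds(resp[, j], K[j]))

  ll_trace <- numeric(0); delta_trace <- numeric(0)
  converged <- FALSE
  ll_prev <- -Inf

  for (cyc in seq_len(control$max_cycles)) {
    plist <- item_prob_list(a, b, nodes)
    es <- estep_patterns(pats, cnt, plist, w)
    post_w <- es$posterior * cnt
    ll_trace <- c(ll_trace, es$loglik)

    a_old <- a; b_old <- b
    njs <- lapply(seq_len(J), function(j)
      expected_counts(pats[, j], post_w, K[j], Q))

    if (constraint == "free") {
      for (j in seq_len(J)) {
        opt <- stats::optim(par_pack(a[j], b[[j]]), neg_q_item, neg_q_grad,
                            nj = njs[[j]], nodes = nodes, method = "BFGS",
                            control = list(maxit = control$m_iter))
        u <- par_unpack(opt$par); a[j] <- u$a; b[[j]] <- u$b
      }
    } else {
      ## thresholds given the (common or fixed) slope
      for (j in seq_len(J)) {
        p0 <- c(b[[j]][1], log(diff(b[[j]])))
        opt <- stats::optim(p0, neg_q_item, neg_q_grad, nj = njs[[j]],
                            nodes = nodes, fixed_a = a[j], method = "BFGS",
                            control = list(maxit = control$m_iter))
        b[[j]] <- cumsum(c(opt$par[1], exp(opt$par[-1])))
      }
      if (constraint == "common") {
        slope_obj <- function(la) {
          aa <- exp(la)
          sum(vapply(seq_len(J), function(j)
            neg_q_item(c(b[[j]][1], log(diff(b[[j]]))), njs[[j]], nodes,
                       fixed_a = aa), numeric(1)))
        }
        a[] <- exp(stats::optimize(slope_obj, c(-3, 3))$minimum)
      }
    }

    delta <- max(abs(c(a - a_old, unlist(b) - unlist(b_old))))
    delta_trace <- c(delta_trace, delta)
    if (delta < control$tol) { converged <- TRUE; break }
    ll_prev <- es$loglik
  }

  ## final log-likelihood at the accepted parameters
  plist <- item_prob_list(a, b, nodes)
  es <- estep_patterns(pats, cnt, plist, w)

  n_params <- switch(constraint,
                     free   = sum(K),
                     common = 1L + sum(K - 1L),
                     fixed  = sum(K - 1L))
  ll <- es$loglik
  items <- lapply(seq_len(J), function(j)
    item_params(data$item_labels[j], a[j], b[[j]]))
  bank <- item_bank(items)

  fit <- structure(list(
    bank = bank, se_bank = NULL, vcov = NULL,
    loglik = ll, deviance = -2 * ll,
    aic = -2 * ll + 2 * n_params,
    bic = -2 * ll + n_params * log(N),
    n_used = N, n_params = n_params,
    converged = converged, n_cycles = length(delta_trace),
    trace = delta_trace, loglik_trace = ll_trace,
    constraint = constraint, grid = grid,
    fingerprint = data_fingerprint(resp)),
    class = "grm_fit")

  if (control$se) {
    se <- tryCatch(opg_standard_errors(pats, cnt, a, b, K, grid, constraint),
                   error = function(e) {
                     warning("standard errors unavailable: ", conditionMessage(e))
                     NULL
                   })
    if (!is.null(se)) {
      fit$se_bank <- se$se_bank
      fit$vcov <- se$vcov
    }
  }
  fit
}

data_fingerprint <- function(resp) {
  c(n = nrow(resp), j = ncol(resp),
    s = sum(resp, na.rm = TRUE), na = sum(is.na(resp)),
    s2 = sum(resp^2, na.rm = TRUE))
}

## ---- empirical (outer-product-of-gradients) information ----------------
## Case-wise score vectors of the marginal log-likelihood, analytic in the
## natural (slope, threshold) space.  Same asymptotic target as supplemented
## EM but computed in one pass from the converged solution.

## per-item derivative arrays: for each category k (0-based), d log P_k / d a
## and d log P_k / d b_m; returned as list of (K x Q) matrices, one per param
item_score_mats <- function(a, b, nodes) {
  Km1 <- length(b); K <- Km1 + 1L; Q <- length(nodes)
  pm <- boundary_matrix(a, b, nodes)           # (K+1) x Q, rows 0..K
  W <- pm * (1 - pm)                           # W_0 = W_K = 0
  P <- pmax(pm[-nrow(pm), , drop = FALSE] - pm[-1, , drop = FALSE], 1e-300)
  ## d P*_k / da = W_k (theta - b_k), boundary rows are constant zero
  dstar_a <- W * rbind(0, outer(-b, nodes, `+`), 0)
  g <- vector("list", K)                       # slope score per category
  ga <- (dstar_a[-nrow(dstar_a), , drop = FALSE] -
           dstar_a[-1, , drop = FALSE]) / P
  out <- list(slope = ga)
  for (m in seq_len(Km1)) {
    gb <- matrix(0, K, Q)
    ## dP*_m/db_m = -a W_m; category m-1 = P*_(m-1) - P*_m gains +a W_m,
    ## category m = P*_m - P*_(m+1) loses it
    gb[m, ]      <-  a * W[m + 1L, ] / P[m, ]
    gb[m + 1L, ] <- -a * W[m + 1L, ] / P[m + 1L, ]
    out[[paste0("b", m)]] <- gb
  }
  out
}

## score matrix: one row per pattern, one column per free parameter
pattern_scores <- function(pats, post, a, b, K, nodes, constraint) {
  J <- length(a); npat <- nrow(pats)
  cols <- list(); colnames_out <- character(0)
  slope_common <- NULL
  for (j in seq_len(J)) {
    sm <- item_score_mats(a[j], b[[j]], nodes)
    idx <- pats[, j]; obs <- !is.na(idx)
    pick <- function(gmat) {
      v <- numeric(npat)
      if (any(obs))
        v[obs] <- rowSums(post[obs, , drop = FALSE] *
                            gmat[idx[obs] + 1L, , drop = FALSE])
      v
    }
    s_slope <- pick(sm$slope)
    if (constraint == "free") {
      cols[[length(cols) + 1L]] <- s_slope
      colnames_out <- c(colnames_out, sprintf("a%d", j))
    } else if (constraint == "common") {
      slope_common <- if (is.null(slope_common)) s_slope
      else slope_common + s_slope
    }
    for (m in seq_len(K[j] - 1L)) {
      cols[[length(cols) + 1L]] <- pick(sm[[paste0("b", m)]])
      colnames_out <- c(colnames_out, sprintf("b%d_%d", j, m))
    }
  }
  if (constraint == "common") {
    cols <- c(list(slope_common), cols)
    colnames_out <- c("a", colnames_out)
  }
  S <- do.call(cbind, cols)
  colnames(S) <- colnames_out
  S
}

opg_standard_errors <- function(pats, cnt, a, b, K, grid, constraint) {
  nodes <- grid$nodes; w <- grid$weights
  plist <- item_prob_list(a, b, nodes)
  es <- estep_patterns(pats, cnt, plist, w)
  S <- pattern_scores(pats, es$posterior, a, b, K, nodes, constraint)
  info <- crossprod(S * sqrt(cnt))
  V <- tryCatch(solve(info), error = function(e)
    stop("empirical information is singular; a larger sample or collapsed ",
         "categories may be needed", call. = FALSE))
  se <- sqrt(diag(V))
  if (any(!is.finite(se)))
    stop("empirical information is singular; a larger sample or collapsed ",
         "categories may be needed", call. = FALSE)
  J <- length(a)
  se_slope <- numeric(J); se_b <- vector("list", J)
  for (j in seq_len(J)) {
    se_slope[j] <- if (constraint == "free") se[sprintf("a%d", j)]
    else if (constraint == "common") se["a"] else NA_real_
    se_b[[j]] <- unname(se[sprintf("b%d_%d", j, seq_len(K[j] - 1L))])
  }
  list(se_bank = list(slope = se_slope, thresholds = se_b),
       vcov = V, info = info)
}

#' Fit the graded response model
#'
#' Bock-Aitkin marginal maximum likelihood with an EM algorithm under a
#' normal latent-trait prior represented by `grid`.  Missing responses are
#' ignorable given the model: the item simply drops out of that
#' respondent's likelihood term.
#'
#' @param data A [response_matrix()].
#' @param grid A [theta_grid()]; default 49 nodes on \[-6, 6\], N(0, 1).
#' @param control A [grm_control()].
#' @return A `grm_fit`: estimated [item_bank()], standard errors,
#'   log-likelihood, AIC/BIC, convergence trace.
#' @examples
#' \donttest{
#' spec <- cohort_spec(group_sizes = c(all = 300), seed = 1)
#' fit <- fit_grm(simulate_cohort(spec))
#' fit$converged
#' }
#' @seealso [fit_rasch()] for the equal-slope restriction, [lr_compare()]
#'   for the nested-model test.
#' @export
fit_grm <- function(data, grid = theta_grid(), control = grm_control()) {
  em_engine(data, grid, constraint = "free", control = control)
}

#' Fit the equal-slope (Rasch-type) restriction
#'
#' Same marginal ML machinery as [fit_grm()], with every item forced to the
#' same discrimination.  `constraint = "common"` estimates the shared slope
#' (J - 1 fewer parameters than the free model); `constraint = "fixed"`
#' pins it at `fixed_slope` (J fewer).
#'
#' @inheritParams fit_grm
#' @param constraint `"common"` (estimated shared slope, the default) or
#'   `"fixed"`.
#' @param fixed_slope Slope value used when `constraint = "fixed"`.
#' @return A `grm_fit`.
#' @export
fit_rasch <- function(data, grid = theta_grid(), control = grm_control(),
                      constraint = c("common", "fixed"), fixed_slope = 1.0) {
  constraint <- match.arg(constraint)
  em_engine(data, grid, constraint = constraint, fixed_slope = fixed_slope,
            control = control)
}

#' Likelihood-ratio comparison of nested fits
#'
#' `delta_chi2 = 2 (loglik_full - loglik_restricted)` referred to a
#' chi-squared distribution with `df` equal to the difference in free
#' parameter counts.  Both fits must come from the same data.
#'
#' @param restricted,full `grm_fit` objects, restricted nested in full.
#' @return A list with `delta_chi2`, `df`, `p`.
#' @export
lr_compare <- function(restricted, full) {
  stopifnot(inherits(restricted, "grm_fit"), inherits(full, "grm_fit"))
  if (!isTRUE(all.equal(restricted$fingerprint, full$fingerprint)))
    stop("fits were not computed on the same data", call. = FALSE)
  if (full$n_params < restricted$n_params)
    stop("`full` has fewer parameters than `restricted`; arguments swapped?",
         call. = FALSE)
  delta <- 2 * (full$loglik - restricted$loglik)
  if (delta < -1e-6)
    warning("restricted fit has higher likelihood than full fit; ",
            "one of the fits has not converged")
  delta <- max(delta, 0)
  df <- full$n_params - restricted$n_params
  p <- if (df == 0L) 1 else stats::pchisq(delta, df, lower.tail = FALSE)
  list(delta_chi2 = delta, df = df, p = p)
}

#' @export
print.grm_fit <- function(x, ...) {
  cat(sprintf("<grm_fit> %s, %d items, N = %d\n",
              switch(x$constraint, free = "graded response model",
                     common = "equal-slope (Rasch-type)",
                     fixed = "fixed-slope (Rasch-type)"),
              length(x$bank), x$n_used))
  cat(sprintf("  -2LL %.2f | AIC %.2f | BIC %.2f | %d params\n",
              x$deviance, x$aic, x$bic, x$n_params))
  cat(sprintf("  %s after %d cycles (last max change %.2g)\n",
              if (x$converged) "converged" else "NOT converged",
              x$n_cycles, utils::tail(x$trace, 1)))
  invisible(x)
}

#' @export
logLik.grm_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_params, nobs = object$n_used,
            class = "logLik")
}

#' @export
coef.grm_fit <- function(object, ...) param_table(object)

#' Parameter table for a fit or bank
#'
#' One row per item: slope, thresholds, slope-intercept values
#' (`c_k = -slope * b_k`) and, when available, standard errors - the shape
#' of a published polytomous-IRT calibration table.
#'
#' @param x A `grm_fit` or `item_bank`.
#' @return A data frame.
#' @export
param_table <- function(x) {
  bank <- if (inherits(x, "grm_fit")) x$bank else x
  stopifnot(inherits(bank, "item_bank"))
  df <- as.data.frame(bank)
  kmax <- max(vapply(bank$items, `[[`, integer(1), "K"))
  for (m in seq_len(kmax - 1L))
    df[[paste0("c", m)]] <- vapply(bank$items, function(it)
      if (m <= it$K - 1L) -it$slope * it$thresholds[m] else NA_real_,
      numeric(1))
  if (inherits(x, "grm_fit") && !is.null(x$se_bank)) {
    df$se_slope <- x$se_bank$slope
    for (m in seq_len(kmax - 1L))
      df[[paste0("se_b", m)]] <- vapply(x$se_bank$thresholds, function(s)
        if (m <= length(s)) s[m] else NA_real_, numeric(1))
  }
  df
}

#' Export a fit as JSON
#'
#' Parameters, standard errors, fit statistics and the convergence trace.
#'
#' @param fit A `grm_fit`.
#' @param path Output path.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "grm_fit"))
  obj <- list(
    model = fit$constraint,
    parameters = param_table(fit),
    loglik = fit$loglik, deviance = fit$deviance,
    aic = fit$aic, bic = fit$bic,
    n_used = fit$n_used, n_params = fit$n_params,
    converged = fit$converged, n_cycles = fit$n_cycles,
    trace = fit$trace)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
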