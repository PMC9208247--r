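## Shared fixtures: small banks built in code and the published reference
## values the calibration is checked against.

tiny_bank <- function() {
  item_bank(
    item_params("t1", 1.2, c(-1.0, 0.5)),
    item_params("t2", 0.8, c(-0.4, 1.1)),
    item_params("t3", 1.6, c(0.0, 0.9)))
}

one_item_bank <- function(slope = 1.5, thresholds = c(-1, 0, 1, 2)) {
  item_bank(item_params("solo", slope, thresholds))
}

## symmetric single item: thresholds symmetric about 0
symmetric_bank <- function() one_item_bank(1.3, c(-1.5, -0.5, 0.5, 1.5))

quick_control <- function(...) grm_control(tol = 1e-3, m_iter = 10L,
                                           max_cycles = 300L, ...)

## enumeration oracle: all response patterns of a small complete bank with
## their marginal probabilities under the N(0,1) prior on `grid`
enumerate_patterns <- function(bank, grid = theta_grid()) {
  Ks <- vapply(bank$items, `[[`, integer(1), "K")
  pats <- as.matrix(expand.grid(lapply(Ks, function(k) 0:(k - 1L))))
  colnames(pats) <- vapply(bank$items, `[[`, character(1), "label")
  lik <- vapply(seq_len(nrow(pats)), function(i) {
    L <- rep(1, length(grid$nodes))
    for (j in seq_along(bank$items)) {
      p <- category_probs(bank$items[[j]], grid$nodes)
      L <- L * p[pats[i, j] + 1L, ]
    }
    sum(L * grid$weights)
  }, numeric(1))
  list(patterns = pats, marginal = lik)
}

## published reference calibration: slopes and thresholds (the relapse
## item's slope corrected to 2.51, see bsas_bank() docs); intercept block
## as printed
published_slopes <- c(1.55, 1.77, 2.85, 4.15, 2.51, 1.93, 3.10)
published_thresholds <- rbind(
  c(-1.32, -0.11, 0.56, 1.83),
  c(-1.25, -0.34, 0.10, 1.76),
  c( 0.27,  1.27, 1.74, 2.56),
  c( 0.11,  0.92, 1.34, 1.96),
  c(-0.16,  0.61, 1.21, 2.17),
  c(-0.21,  0.75, 1.30, 2.66),
  c( 0.44,  1.17, 1.61, 2.40))
published_intercepts <- rbind(
  c( 2.05,  0.18, -0.87, -2.83),
  c( 2.20,  0.60, -0.17, -3.12),
  c(-0.78, -3.62, -4.96, -7.31),
  c(-0.48, -3.82, -5.55, -8.14),
  c( 0.41, -1.54, -3.04, -5.44),
  c( 0.40, -1.44, -2.51, -5.15),
  c(-1.37, -3.64, -4.99, -7.44))

## published information grid: theta from -2.8 to 2.8 by 0.4; 7 item rows,
## then test information and expected standard error
published_info_thetas <- seq(-2.8, 2.8, by = 0.4)
published_iif <- rbind(
  c(0.20,0.32,0.47,0.60,0.68,0.71,0.73,0.74,0.74,0.72,0.70,0.68,0.62,0.50,0.36),
  c(0.18,0.32,0.52,0.74,0.88,0.95,0.97,0.94,0.86,0.79,0.79,0.83,0.76,0.58,0.37),
  c(0.00,0.00,0.01,0.04,0.12,0.35,0.90,1.77,2.16,2.07,2.34,2.47,2.31,2.25,1.86),
  c(0.00,0.00,0.00,0.01,0.07,0.37,1.63,4.13,3.99,4.56,5.12,4.63,4.47,2.06,0.50),
  c(0.01,0.02,0.06,0.16,0.40,0.89,1.49,1.80,1.88,1.93,1.88,1.75,1.73,1.48,0.89),
  c(0.02,0.05,0.11,0.22,0.42,0.69,0.95,1.08,1.12,1.15,1.13,1.05,0.99,1.01,0.95),
  c(0.00,0.00,0.00,0.02,0.06,0.20,0.62,1.56,2.54,2.70,2.89,2.87,2.63,2.56,1.68))
published_test_info <- c(1.41,1.72,2.18,2.79,3.63,5.14,8.28,13.03,14.30,14.92,
                         15.85,15.27,14.52,11.45,7.61)
published_expected_se <- c(0.84,0.76,0.68,0.60,0.52,0.44,0.35,0.28,0.26,0.26,
                           0.25,0.26,0.26,0.30,0.36)

## published summed-score EAP conversion table (scores 0..28)
published_score_table <- data.frame(
  summed_score = 0:28,
  eap = c(-1.389,-0.861,-0.556,-0.364,-0.175,0.005,0.158,0.299,0.429,0.547,
          0.657,0.762,0.864,0.964,1.064,1.163,1.262,1.362,1.462,1.564,1.669,
          1.778,1.895,2.020,2.156,2.306,2.478,2.697,3.022),
  sd = c(0.610,0.481,0.431,0.422,0.383,0.346,0.323,0.301,0.283,0.270,0.261,
         0.255,0.251,0.247,0.245,0.243,0.242,0.241,0.241,0.241,0.243,0.245,
         0.248,0.253,0.259,0.268,0.284,0.320,0.402),
  modelled_proportion = c(0.1295,0.1155,0.0949,0.0838,0.0731,0.0618,0.0535,
                          0.0470,0.0418,0.0375,0.0338,0.0303,0.0271,0.0242,
                          0.0215,0.0191,0.0170,0.0151,0.0133,0.0117,0.0102,
                          0.0087,0.0073,0.0061,0.0049,0.0039,0.0031,0.0024,
                          0.0016))
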