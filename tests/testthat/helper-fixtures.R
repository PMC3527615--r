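# shared fixtures, built once per test run

fixture_seasonal <- generate_seasonal(generator_config(seed = 42))
fixture_spatial <- generate_spatial(generator_config(seed = 7))

# central finite-difference Jacobian, the independent oracle for the
# analytic residual derivatives
fd_jacobian <- function(net, X, h = 1e-6) {
  p <- length(net$theta)
  J <- matrix(0, nrow(X), p)
  for (k in seq_len(p)) {
    up <- net; up$theta[k] <- up$theta[k] + h
    dn <- net; dn$theta[k] <- dn$theta[k] - h
    J[, k] <- (ann_forward(up, X) - ann_forward(dn, X)) / (2 * h)
  }
  J
}

# closed-form simple linear regression (normal equations), independent of lm
ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  s2 <- sum(res^2) / (n - 2)
  list(intercept = intercept, slope = slope,
       se_slope = sqrt(s2 / sxx),
       se_intercept = sqrt(s2 * (1 / n + mean(x)^2 / sxx)),
       r2 = sxy^2 / (sxx * sum((y - mean(y))^2)))
}

# printed summary moments of the two field campaigns (calibration ground
# truth used across generator tests)
printed_seasonal <- list(
  cv = c(temperature_c = 57.2, salinity_psu = 5.1, day_length_h = 66.7,
         chl_a_ug_l = 132.7, hna_1e5_ml = 72.9, lna_1e5_ml = 53.0,
         prokaryotes_1e5_ml = 62.7, v1_1e6_ml = 87.4, v2_1e6_ml = 60.4,
         viruses_1e6_ml = 63.4),
  min = c(chl_a_ug_l = 0.01, hna_1e5_ml = 0.44, lna_1e5_ml = 0.80,
          v1_1e6_ml = 0.16, v2_1e6_ml = 0.90, prokaryotes_1e5_ml = 1.32,
          viruses_1e6_ml = 1.27),
  max = c(chl_a_ug_l = 0.61, hna_1e5_ml = 9.49, lna_1e5_ml = 6.04,
          v1_1e6_ml = 4.08, v2_1e6_ml = 16.11, prokaryotes_1e5_ml = 15.54,
          viruses_1e6_ml = 19.96))

printed_spatial <- list(
  # salinity CV from the printed Avg/SD (100 * 4.33 / 28.78)
  cv = c(temperature_c = 282.5, salinity_psu = 15.0, day_length_h = 7.2,
         chl_a_ug_l = 121.6, hna_1e5_ml = 48.4, lna_1e5_ml = 49.5,
         prokaryotes_1e5_ml = 47.5, v1_1e6_ml = 77.4, v2_1e6_ml = 44.9,
         viruses_1e6_ml = 47.3),
  min = c(chl_a_ug_l = 0.07),
  max = c(chl_a_ug_l = 2.37, hna_1e5_ml = 13.65, lna_1e5_ml = 9.19,
          v1_1e6_ml = 5.35, v2_1e6_ml = 23.20, prokaryotes_1e5_ml = 22.71,
          viruses_1e6_ml = 28.55))
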