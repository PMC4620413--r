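# Shared fixtures for the test suite.

# Published repeated-run results of the tuned classifier on the CT cohort
# (16 positives / 40 negatives in the test split): per-run C, gamma, FPR
# and FNR, with the printed accuracy/precision/F1 percentages used as
# frozen expectations.
ct_runs <- data.frame(
  C = c(0.8666, 0.7089, 0.7015, 0.8605, 0.9922, 0.8319, 0.6345, 0.9405,
        0.7671, 0.6504),
  gamma = c(878.79, 1003.4, 952.7641, 1401.3, 1314, 1364.5, 1050.6,
            820.0642, 1384.7, 1509.8),
  fpr = c(0, 0.025, 0.025, 0.05, 0.05, 0.05, 0.025, 0, 0.05, 0.125),
  fnr = rep(0, 10),
  accuracy_pct = c(100.00, 98.21, 98.21, 96.43, 96.43, 96.43, 98.21,
                   100.00, 96.43, 91.07),
  precision_pct = c(100.00, 94.12, 94.12, 88.89, 88.89, 88.89, 94.12,
                    100.00, 88.89, 76.19),
  f1_pct = c(100.00, 96.97, 96.97, 94.12, 94.12, 94.12, 96.97, 100.00,
             94.12, 86.49)
)
ct_test_pos <- 16L
ct_test_neg <- 40L

# Zoom multiples appropriate for the standardized synthetic Gaussian
# features (prior knowledge of that cohort): C in (0, 10], gamma in (0, 1].
synthetic_zoom <- function() zoom_config(c_multiple = 10, gamma_multiple = 1)

# A small, cleanly separable cohort for fast tuner tests.
small_separable <- function(seed = 1L) {
  generate_feature_dataset(
    synthetic_spec(n_pos_train = 10, n_neg_train = 20, n_pos_test = 8,
                   n_neg_test = 16, dims = 4, separation = 6, seed = seed)
  )
}

quadratic_objective <- function(s) (s[1] - 0.4)^2 + (s[2] - 0.6)^2

quadratic_grid_minimum <- function() {
  g <- expand.grid(s1 = seq(0, 1, length.out = 101),
                   s2 = seq(0, 1, length.out = 101))
  min((g$s1 - 0.4)^2 + (g$s2 - 0.6)^2)
}
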