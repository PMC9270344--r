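# In-code fixtures and independent oracles shared across test files.

# A tiny anomaly_dataset built directly (no preprocessing), with iid normal
# anomalies and a fully-true validity mask unless given.
make_anomaly_dataset <- function(n_time = 100L, n_lat = 4L, n_lon = 4L,
                                 seed = 7L, lai_fun = NULL, mask = NULL) {
  set.seed(seed)
  time <- month_seq_ext(2000L, 2000L + ceiling(n_time / 12) - 1L)[seq_len(n_time)]
  lat <- 40 + 0.5 * seq_len(n_lat)
  lon <- 10 + 0.5 * seq_len(n_lon)
  dims <- c(n_time, n_lat, n_lon)
  mk <- function(name) grid_field(array(rnorm(prod(dims)), dims), "mm",
                                  time, lat, lon, name)
  fields <- list(smnear = mk("smnear"), smsub = mk("smsub"), temp = mk("temp"),
                 precip = mk("precip"), vpd = mk("vpd"), rad = mk("rad"))
  lai_vals <- if (is.null(lai_fun)) array(rnorm(prod(dims)), dims)
  else lai_fun(fields)
  fields$lai <- grid_field(lai_vals, "m2/m2", time, lat, lon, "lai")
  if (is.null(mask)) mask <- array(TRUE, dims)
  structure(c(fields[c("lai", "smnear", "smsub", "temp", "precip", "vpd",
                       "rad")],
              list(valid_mask = mask, time = time, lat = lat, lon = lon)),
            class = "anomaly_dataset")
}

month_seq_ext <- function(y0, y1) {
  seq(as.Date(sprintf("%d-01-01", y0)), as.Date(sprintf("%d-12-01", y1)),
      by = "month")
}

# Brute-force Theil-Sen: explicit double loop over all pairs.
theil_sen_bruteforce <- function(x, y) {
  slopes <- c()
  n <- length(x)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (x[j] != x[i]) slopes <- c(slopes, (y[j] - y[i]) / (x[j] - x[i]))
  median(slopes)
}

# Brute-force Mann-Kendall S and tie-corrected variance by pair enumeration.
mann_kendall_bruteforce <- function(y) {
  n <- length(y)
  S <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) S <- S + sign(y[j] - y[i])
  tie_term <- 0
  for (v in unique(y)) {
    t <- sum(y == v)
    if (t > 1) tie_term <- tie_term + t * (t - 1) * (2 * t + 5)
  }
  list(S = S, var_S = (n * (n - 1) * (2 * n + 5) - tie_term) / 18)
}

# Conditional expectation of one tree given a feature subset S (1-based
# indices of "present" features), marginalizing absent features by cover flow.
tree_cond_exp <- function(tree, x, S) {
  rec <- function(node) {
    if (tree$left[node] < 0) return(tree$value[node])
    f <- tree$feature[node] + 1L
    l <- tree$left[node] + 1L
    r <- tree$right[node] + 1L
    if (f %in% S) {
      if (x[f] <= tree$threshold[node]) rec(l) else rec(r)
    } else {
      (tree$cover[l] * rec(l) + tree$cover[r] * rec(r)) / tree$cover[node]
    }
  }
  rec(1L)
}

# Exact Shapley values of a forest by full subset enumeration (2^p subsets).
shapley_bruteforce <- function(trees, x) {
  p <- length(x)
  phi <- numeric(p)
  for (tree in trees) {
    for (i in seq_len(p)) {
      others <- setdiff(seq_len(p), i)
      for (mask in 0:(2^(p - 1) - 1)) {
        S <- others[bitwAnd(mask, 2^(seq_len(p - 1) - 1)) > 0]
        k <- length(S)
        w <- factorial(k) * factorial(p - k - 1) / factorial(p)
        phi[i] <- phi[i] + w * (tree_cond_exp(tree, x, c(S, i)) -
                                  tree_cond_exp(tree, x, S))
      }
    }
  }
  phi / length(trees)
}

# Fit a small forest on a data.frame-like table for SHAP tests.
fit_small_rf <- function(X, y, ntree = 5L, nodesize = 10L, seed = 42L) {
  set.seed(seed)
  randomForest::randomForest(X, y, ntree = ntree, mtry = 2, nodesize = nodesize,
                             keep.forest = TRUE, keep.inbag = TRUE)
}
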