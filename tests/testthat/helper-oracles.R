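# Independent brute-force oracles, deliberately naive implementations.

# Windowed mean/SD over a circular window with explicit symmetric
# (edge-repeating) reflected padding, computed pixel by pixel.
brute_local_stats <- function(x, radius) {
  n <- nrow(x); m <- ncol(x)
  ri <- c(rev(seq_len(radius)), seq_len(n), n + 1 - seq_len(radius))
  ci <- c(rev(seq_len(radius)), seq_len(m), m + 1 - seq_len(radius))
  xp <- x[ri, ci]
  offs <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  offs <- offs[offs$dr^2 + offs$dc^2 <= radius^2, ]
  mu <- sd_ <- matrix(NA_real_, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    vals <- xp[cbind(i + radius + offs$dr, j + radius + offs$dc)]
    mu[i, j] <- mean(vals)
    sd_[i, j] <- sqrt(mean((vals - mean(vals))^2))  # population SD
  }
  list(mean = mu, sd = sd_)
}

# Per-tile CCFA ratios by explicit double loop.
brute_tile_ratios <- function(p, order) {
  th <- nrow(p) %/% order; tw <- ncol(p) %/% order
  out <- matrix(NA_real_, order, order)
  for (i in seq_len(order)) for (j in seq_len(order)) {
    tile <- p[(i - 1) * th + seq_len(th), (j - 1) * tw + seq_len(tw)]
    out[i, j] <- 100 * sum(tile) / length(tile)
  }
  out
}

# Exact two-sided Mann-Whitney p by full enumeration of all assignments of
# the pooled (distinct) values to the two groups.
enum_mwu_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_stat <- function(xs, ys) sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  u_obs <- u_stat(x, y)
  combs <- utils::combn(length(pooled), n1)
  mu <- n1 * (length(pooled) - n1) / 2
  us <- apply(combs, 2, function(ix) u_stat(pooled[ix], pooled[-ix]))
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Hypergeometric two-sided Fisher p: sum of probabilities of all tables
# with the observed margins whose point probability <= observed.
enum_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(xs, r1, r2, c1)
  p_obs <- dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Small cohort table with prescribed group effects, used by stats-level
# tests that do not need images.
make_metric_cohort <- function(n_amd = 38, n_control = 22,
                               ccfa_means = c(amd_fellow = 58.1, control = 62.9),
                               cv_means = c(amd_fellow = 0.182, control = 0.152),
                               ccfa_se = c(amd_fellow = 1.0, control = 1.4),
                               cv_se = c(amd_fellow = 0.007, control = 0.0061)) {
  g <- c(rep("amd_fellow", n_amd), rep("control", n_control))
  nn <- c(amd_fellow = n_amd, control = n_control)
  data.frame(
    id = sprintf("s%02d", seq_along(g)), group = g,
    age = round(rnorm(length(g), 70, 10), 1),
    sex = sample(c("male", "female"), length(g), replace = TRUE),
    faf_abnormal = c(runif(n_amd) < 9 / 38, rep(FALSE, n_control)),
    asymmetric_vasculature = runif(length(g)) < 0.4,
    thicker_side = "none",
    ccfa_ratio = rnorm(length(g), ccfa_means[g], (ccfa_se * sqrt(nn))[g]),
    cv = rnorm(length(g), cv_means[g], (cv_se * sqrt(nn))[g]),
    stringsAsFactors = FALSE)
}

# Logistic-recovery generator: binary outcome with a known exposure
# log-odds plus age and sex effects.
simulate_logistic_cohort <- function(n = 600, or_exposure = 5.408,
                                     beta_age = 0.03, beta_sex = 0.3,
                                     intercept = -1.6) {
  exposure <- runif(n) < 0.35
  age <- rnorm(n, 70, 10)
  sex <- runif(n) < 0.5
  lp <- intercept + log(or_exposure) * exposure +
    beta_age * (age - 70) + beta_sex * sex
  y <- runif(n) < plogis(lp)
  data.frame(y = y, exposure = exposure, age = age,
             sex = ifelse(sex, "male", "female"))
}
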