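test_that("psychometric function matches direct numerical quadrature", {
  # independent oracle: integrate the Gaussian density of the internal
  # difference measurement from 0 to Inf
  quad <- function(delta, sigma, mu = 0)
    integrate(function(x) dnorm(x, mean = delta - mu, sd = sigma),
              0, Inf, rel.tol = 1e-12)$value
  set.seed(41)
  cases <- expand.grid(delta = c(-6, -2, -0.5, 0, 0.5, 2, 6),
                       sigma = c(0.3, 1, 2, 5, 14),
                       mu = c(-3, 0, 1.5))
  for (i in seq_len(nrow(cases))) {
    expect_equal(psychometric_prob(cases$delta[i], cases$sigma[i],
                                   cases$mu[i]),
                 quad(cases$delta[i], cases$sigma[i], cases$mu[i]),
                 tolerance = 1e-8)
  }
  expect_equal(psychometric_prob(2, 2), pnorm(1))
  expect_equal(psychometric_prob(1.5, 3, 1.5), 0.5)
  expect_equal(psychometric_prob(1e6, 2), 1)
  expect_equal(psychometric_prob(-1e6, 2), 0)
  expect_error(psychometric_prob(1, -2), "positive")
})

test_that("condition likelihood equals the brute-force product", {
  d <- condition_data(c(1, -1), k = c(15, 5), n = c(20, 20))
  for (sg in c(0.7, 2, 9)) {
    for (mu in c(-1, 0, 2)) {
      expect_equal(condition_likelihood(d, sg, mu, log = FALSE),
                   oracle_likelihood(d, sg, mu), tolerance = 1e-12)
    }
  }
  # vectorised over sigma
  sgs <- c(0.5, 1, 2, 4, 8)
  expect_equal(condition_likelihood(d, sgs, log = FALSE),
               sapply(sgs, function(s) oracle_likelihood(d, s)))
  # single Bernoulli trial and empty product
  d1 <- condition_data(2, k = 1, n = 1)
  expect_equal(condition_likelihood(d1, 2, log = FALSE),
               psychometric_prob(2, 2))
  d0 <- condition_data(numeric(0), numeric(0), numeric(0))
  expect_equal(condition_likelihood(d0, 2), 0)
  # a practically impossible response yields a huge negative but finite
  # log-likelihood (no exception); an exact zero maps to the -745 guard
  dimp <- condition_data(-50, k = 20, n = 20)
  ll <- condition_likelihood(dimp, 0.5)
  expect_true(is.finite(ll) && ll < -1e5)
  expect_equal(hapticue:::floor_loglik(c(-Inf, -3)), c(-745, -3))
})

test_that("likelihood scaling invariance: posteriors unchanged", {
  set.seed(42)
  d <- closed_form_data(c(-5, -2, -1, -0.5, 0.5, 1, 2, 5), 20, 3)
  p1 <- sigma_posterior(d)
  # doubling every count multiplies the log-likelihood by 2 (not a scale
  # factor), but multiplying the likelihood by a constant must not change
  # the posterior: emulate by adding a constant to the log-likelihood
  grid <- default_sigma_grid()
  ll <- condition_likelihood(d, sqrt(2) * grid)
  w <- exp(ll + 123 - max(ll + 123))
  expect_equal(p1$prob, w / sum(w), tolerance = 1e-12)
  expect_prob_vector(p1$prob)
})

test_that("sigma posterior reverts to the prior without evidence", {
  d <- condition_data(c(-1, 1), k = c(0, 0), n = c(0, 0))
  p <- sigma_posterior(d)
  expect_prob_vector(p$prob)
  expect_equal(p$prob, rep(1 / length(p$grid), length(p$grid)))
})

test_that("sigma posterior modes order by cue reliability (varied sigmas)", {
  set.seed(43)
  sim <- simulant(sig_varied(), "OPT")
  modes <- replicate(20, {
    dat <- run_experiment(sim, quick_design())
    sapply(dat$conditions[c("Thumb", "Index", "Config")], function(d) {
      p <- sigma_posterior(d)
      p$grid[which.max(p$prob)]
    })
  })
  m <- rowMeans(modes)
  expect_lt(m[["Config"]], m[["Index"]])
  expect_lt(m[["Index"]], m[["Thumb"]])
})

test_that("credible intervals cover the generating sigma", {
  set.seed(44)
  deltas <- c(-5, -2, -1, -0.5, 0.5, 1, 2, 5)
  # sigmas well inside the range the +/-5 mm deltas can identify
  for (s_true in c(1.5, 3)) {
    hits <- replicate(60, {
      d <- closed_form_data(deltas, 20, s_true)
      p <- sigma_posterior(d)
      cdf <- cumsum(p$prob)
      lo <- p$grid[which(cdf >= 0.025)[1]]
      hi <- p$grid[which(cdf >= 0.975)[1]]
      s_true >= lo && s_true <= hi
    })
    expect_gte(mean(hits), 0.85)
  }
})

test_that("posterior sampling matches the posterior CDF", {
  # point mass: every draw equals the supported grid value
  g <- default_sigma_grid()
  pm <- hapticue:::new_sigma_posterior(g, as.numeric(g == g[300]))
  expect_equal(sample_sigmas(pm, 50), rep(g[300], 50))
  # uniform posterior: symmetric around the grid midpoint
  set.seed(45)
  un <- hapticue:::uniform_sigma_posterior(g)
  dr <- sample_sigmas(un, 1e5)
  expect_equal(mean(dr), mean(range(g)), tolerance = 0.05)
  # KS distance between draws and the posterior CDF on a peaked posterior
  d <- closed_form_data(c(-5, -2, -1, -0.5, 0.5, 1, 2, 5), 20, 3)
  p <- sigma_posterior(d)
  dr <- sample_sigmas(p, 1e4)
  cdf_post <- stats::stepfun(p$grid, c(0, cumsum(p$prob)))
  ks <- max(abs(ecdf(dr)(p$grid) - cdf_post(p$grid)))
  expect_lt(ks, 0.02)
})

test_that("joint posterior localizes mu and reflects under label swap", {
  set.seed(46)
  deltas <- c(-5, -2, -1, -0.5, 0.5, 1, 2, 5)
  d <- closed_form_data(deltas, 200, 2, mu = 1.2)
  jp <- joint_posterior(d)
  expect_prob_vector(as.vector(jp$prob))
  expect_lt(abs(pse_estimate(jp) - 1.2), 0.4)
  # swapping k -> n - k at symmetric levels reflects the mu marginal
  d2 <- condition_data(-rev(d$delta), rev(d$n - d$k), rev(d$n))
  jp2 <- joint_posterior(d2)
  expect_equal(rowSums(jp$prob), rev(rowSums(jp2$prob)), tolerance = 1e-9)
  expect_equal(pse_estimate(jp2), -pse_estimate(jp))
})

test_that("PSE estimate is the mu-marginal mode with |mu| tie-break", {
  mu <- default_mu_grid(); sg <- default_sigma_grid()
  pt <- matrix(0, length(mu), length(sg))
  pt[which(mu == 1.5), 40] <- 1
  expect_equal(pse_estimate(hapticue:::new_joint_posterior(mu, sg, pt)), 1.5)
  # exactly symmetric bimodal marginal: tie resolves toward smallest |mu|
  bi <- matrix(0, length(mu), length(sg))
  bi[which(mu == -2), 40] <- 0.5
  bi[which(mu == 2), 40] <- 0.5
  expect_equal(pse_estimate(hapticue:::new_joint_posterior(mu, sg, bi)), -2)
  flat <- hapticue:::uniform_joint_posterior(mu, sg)
  expect_equal(abs(pse_estimate(flat)), 0)
})

test_that("conflict mu recovery matches the OPT slope prediction", {
  set.seed(47)
  s <- sig_varied()
  target <- pse_slope("OPT", s) * 3   # +1.185
  reps <- 20
  modes <- replicate(reps, {
    sim <- simulant(s, "OPT")
    dat <- run_experiment(sim, conflict_design(conflicts = 3))
    pse_estimate(joint_posterior(dat$conditions[["Conflict+3"]]))
  })
  expect_lt(abs(mean(modes) - target), 3 * sd(modes) / sqrt(reps))
})

test_that("adaptive selection maximizes brute-force expected entropy gain", {
  # independent oracle: loop over candidates, responses and grid points
  oracle_select <- function(post, candidates) {
    H <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
    gains <- sapply(candidates, function(delta) {
      psi <- pnorm(delta / (sqrt(2) * post$grid))
      p1 <- sum(post$prob * psi)
      g1 <- if (p1 > 0) p1 * H(post$prob * psi / p1) else 0
      g0 <- if (p1 < 1) (1 - p1) * H(post$prob * (1 - psi) / (1 - p1)) else 0
      H(post$prob) - (g1 + g0)
    })
    candidates[which.max(gains)]
  }
  g <- default_sigma_grid()
  un <- hapticue:::uniform_sigma_posterior(g)
  cands <- c(-0.5, 0.5, -5, 5)
  expect_equal(select_next_stimulus(un, cands), oracle_select(un, cands))
  set.seed(48)
  d <- closed_form_data(c(-2, -1, 1, 2), 10, 3)
  p <- sigma_posterior(d)
  for (cset in list(c(-0.5, 0.5, -5, 5), c(2, 4, 8), c(-1, 1)))
    expect_equal(select_next_stimulus(p, cset), oracle_select(p, cset))
  # point-mass posterior: all gains zero, first candidate returned
  pm <- hapticue:::new_sigma_posterior(g, as.numeric(g == g[100]))
  expect_equal(select_next_stimulus(pm, c(3, 1, -1)), 3)
  # symmetric posterior, symmetric candidates: first listed wins the tie
  expect_equal(select_next_stimulus(un, c(-2, 2)), -2)
  expect_error(select_next_stimulus(un, numeric(0)), "non-empty")
})

test_that("adaptive schedules beat MCS posterior entropy on average", {
  set.seed(49)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  reps <- 100
  res <- replicate(reps, {
    sim <- simulant(cue_sigmas(7, 6, 3), "OPT")
    des_a <- experiment_design(trials_per_level = 8L, schedule = "adaptive",
                               conditions = "Config")
    des_m <- experiment_design(trials_per_level = 8L, conditions = "Config")
    pa <- sigma_posterior(run_experiment(sim, des_a)$conditions$Config)
    pm <- sigma_posterior(run_experiment(sim, des_m)$conditions$Config)
    c(ent(pa$prob), ent(pm$prob))
  })
  expect_lt(mean(res[1, ]), mean(res[2, ]))
})

test_that("posterior export writes a readable grid table", {
  set.seed(50)
  d <- closed_form_data(c(-2, 2), 20, 3)
  p <- sigma_posterior(d)
  path <- withr::local_tempfile(fileext = ".csv")
  write_posterior(p, path)
  back <- read.csv(path)
  expect_equal(back$sigma, p$grid)
  expect_equal(back$probability, p$prob, tolerance = 1e-12)
})

test_that("mu-mode RMSE shrinks as trials per level grow", {
  set.seed(51)
  deltas <- c(-5, -2, -1, -0.5, 0.5, 1, 2, 5)
  rmse <- sapply(c(5, 20, 80), function(npl) {
    err <- replicate(30, {
      d <- closed_form_data(deltas, npl, 2.5, mu = 1)
      pse_estimate(joint_posterior(d)) - 1
    })
    sqrt(mean(err^2))
  })
  # monotone decrease within simulation error: allow tiny slack
  expect_lt(rmse[2], rmse[1] + 0.05)
  expect_lt(rmse[3], rmse[2] + 0.05)
  expect_lt(rmse[3], rmse[1])
})
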