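# Independent oracles and fixture builders shared across the test files.

# straight-line composite oracle: triple loop over domains, items and the
# chosen option's standardised value; independent of composite_score()
oracle_composite <- function(config, responses) {
  total <- 0
  for (d in config$domains) {
    for (it in d$items) {
      rank <- responses$answers[[it$id]]
      r <- NA_real_
      for (o in it$options) if (o$severity_rank == rank) r <- o$value
      total <- total + (d$weight_pct / 100) * (it$weight_pct / 100) * r * 100
    }
  }
  total
}

# linear-interpolation quantile oracle: q_p = x_(i) + (h - floor(h)) *
# (x_(i+1) - x_(i)) with h = (n - 1) p on the sorted sample (1-based i =
# floor(h) + 1); written from the formula, not via stats::quantile
oracle_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  vapply(p, function(pp) {
    h <- (n - 1) * pp
    i <- floor(h)
    lo <- x[i + 1]
    if (i + 2 > n) lo else lo + (h - i) * (x[i + 2] - lo)
  }, numeric(1))
}

# random valid instrument configuration (weights need not be integers but sum
# to 100 at both levels; option values anchored at 0 and 1, non-decreasing)
random_config <- function(seed) {
  set.seed(seed)
  n_dom <- sample(2:4, 1)
  setting <- if (n_dom == 4) "prophylaxis" else "on_demand"
  dnames <- sample(c("bleeding_episodes", "joint_health", "adherence_qol",
                     if (n_dom == 4) "pharmacokinetics"), n_dom)
  W <- as.numeric(rmultinom(1, 100, rep(1, n_dom)))
  while (any(W == 0)) W <- as.numeric(rmultinom(1, 100, rep(1, n_dom)))
  domains <- lapply(seq_len(n_dom), function(di) {
    n_it <- sample(1:3, 1)
    w <- if (n_it == 1) 100 else {
      ww <- as.numeric(rmultinom(1, 100, rep(1, n_it)))
      while (any(ww == 0)) ww <- as.numeric(rmultinom(1, 100, rep(1, n_it)))
      ww
    }
    its <- lapply(seq_len(n_it), function(ii) {
      k <- sample(c(3L, 4L), 1)
      vals <- c(0, sort(runif(k - 2)), 1)
      opts <- lapply(seq_len(k), function(oi) {
        response_option(sprintf("opt%d", oi), oi - 1L, vals[oi])
      })
      instrument_item(sprintf("d%d_i%d", di, ii), "q", k, w[ii], opts)
    })
    instrument_domain(sprintf("d%d", di), dnames[di], W[di], its)
  })
  instrument_config(disease = sample(c("A", "B"), 1), setting = setting,
                    domains = domains)
}

# uniformly random complete response set for a configuration
random_responses <- function(config, seed) {
  set.seed(seed)
  items <- unlist(lapply(config$domains, function(d) d$items), recursive = FALSE)
  answers <- vapply(items, function(it) {
    sample.int(it$scale_size, 1) - 1L
  }, integer(1))
  names(answers) <- vapply(items, function(it) it$id, character(1))
  response_set("p1", config$disease, config$setting, answers)
}

bundled_configs <- function() {
  list(
    A_prophylaxis = load_instrument("A", "prophylaxis"),
    B_prophylaxis = load_instrument("B", "prophylaxis"),
    A_on_demand = load_instrument("A", "on_demand"),
    B_on_demand = load_instrument("B", "on_demand")
  )
}
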