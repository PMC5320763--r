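# shared fixture builders (everything is generated in code; no data files)

# two-class records with one perfectly discriminating categorical feature
# among noise features
make_class_data <- function(n, seed, n_noise_num = 2, n_noise_cat = 2) {
  set.seed(seed)
  d <- data.frame(sig = sample(c("A", "B"), n, TRUE))
  for (i in seq_len(n_noise_num)) d[[paste0("num", i)]] <- rnorm(n)
  for (i in seq_len(n_noise_cat))
    d[[paste0("cat", i)]] <- sample(letters[1:(4 + i)], n, TRUE)
  d$occ <- ifelse(d$sig == "A", "presence", "absence")
  d
}

# small mixed-feature spec table with unit weights and known SDs
make_specs <- function(sd_a = 1) {
  structure(data.frame(name = c("num_a", "cat_b"),
                       kind = c("numeric", "categorical"),
                       weight = c(1, 1), sd = c(sd_a, NA),
                       stringsAsFactors = FALSE),
            class = c("feature_specs", "data.frame"))
}

# a tiny landscape/record pair for pipeline-ish tests
make_demo_observations <- function(seed = 7, ...) {
  cfg <- synth_config(seed = seed, ...)
  ls <- generate_landscape(cfg)
  obs <- generate_observations(ls, cfg)
  list(cfg = cfg, landscape = ls, records = obs$records, truth = obs$truth)
}

# brute-force budget-k retrieval oracle: rank all similarities descending
# (ties by id), accumulate until the budget is reached
oracle_decision <- function(ts, k, ids = seq_along(ts)) {
  usable <- which(!is.na(ts) & ts > 0)
  if (length(usable) == 0) return(NULL)
  o <- usable[order(-ts[usable], ids[usable])]
  cum <- cumsum(ts[o])
  m <- which(cum >= k)[1]
  exhausted <- is.na(m)
  if (exhausted) m <- length(o)
  list(ids = ids[o[seq_len(m)]], ts = ts[o[seq_len(m)]],
       cumulative = cum[m], exhausted = exhausted)
}
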