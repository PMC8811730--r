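# Shared synthetic fixtures, generated once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# the study-size dataset: 20 experiments, 5 archetypes, seed 7
study_dataset <- function(sigma = 0.02) {
  cached(paste0("study_", sigma),
         suppressMessages(generate_dataset(20, seed = 7, noise_sigma = sigma)))
}

pooled_rates <- function(ds) {
  suppressMessages(suppressWarnings(
    bind_rate_tables(lapply(ds$experiments, compute_rate_vectors))))
}

study_rates <- function(sigma = 0.02) {
  cached(paste0("rates_", sigma), pooled_rates(study_dataset(sigma)))
}

join_key <- function(e, t) paste(e, round(as.numeric(t), 6))

# planted archetype index for each row of a rate-matrix ids frame
truth_labels <- function(ids, truth) {
  truth$archetype[match(join_key(ids$experiment_id, ids$time_h),
                        join_key(truth$experiment_id, truth$time_h))]
}

truth_rates <- function(ids, truth, dims) {
  as.matrix(truth[match(join_key(ids$experiment_id, ids$time_h),
                        join_key(truth$experiment_id, truth$time_h)),
                  dims, drop = FALSE])
}

# a cluster model whose reference phenotypes are given directly
make_model <- function(centroids, labels = integer(0), metric = "cd") {
  structure(list(method = "kmeans", metric = metric, k = nrow(centroids),
                 labels = labels, ids = NULL, z_centroids = NULL,
                 raw_centroids = centroids, objective = NA_real_,
                 params = list(), diagnostics = NULL),
            class = "cluster_model")
}

# single-archetype experiment with constant planted rates, for closed-loop
# rate recovery at known ground truth
constant_rate_config <- function(arch, dur = 12, n_samp = 13, sigma = 0,
                                 init = c(BM = 0.2, Gly = 500, Glc = 200),
                                 id = "const") {
  simulation_config(
    experiment_id = id,
    schedule = data.frame(start = 0, end = dur, archetype = 1),
    archetypes = list(arch), init = init,
    sample_times = seq(0, dur, length.out = n_samp),
    noise_sigma = sigma)
}

# a rate table + model with fully controlled labels and tags, for the
# conditionality statistic
fake_population <- function(labels, tag_values, cum = NULL) {
  n <- length(labels)
  rt <- data.frame(experiment_id = sprintf("e%04d", seq_len(n)),
                   time_h = seq_len(n), mu = 0.1, r_PDO = 1,
                   c_PDO = seq_len(n), c_BM = 0.2,
                   tag_cond = tag_values, stringsAsFactors = FALSE)
  if (!is.null(cum)) rt$cum_PDO <- cum
  class(rt) <- c("rate_table", "data.frame")
  model <- align_assignments(
    data.frame(experiment_id = rt$experiment_id, time_h = rt$time_h,
               cluster = labels), rt)
  list(rates = rt, model = model)
}
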