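#' Run a named analysis stage (or a recipe of stages) from a config
#'
#' Stages chain the workflow pieces: `simulate-hopfield` (patterns +
#' Hebbian couplings + Glauber sampling, writes a state-series TSV),
#' `cluster` (mean-shift pipeline, writes a clusters JSON), `infer` (MPF,
#' full or reduced, writes a fit JSON), `simulate-spiking` (modular
#' network simulation, writes a two-column spike raster and optionally the
#' binarized word series; architecture keys are taken from the config
#' block), `learn-correlations` (pseudo-Boltzmann learning against the
#' statistics of a target word series, writes the trajectory and final
#' parameters), `symdyn` (labeling + complexity, writes a report JSON),
#' `fixtures` (writes a fixture dataset). A provenance JSON (parameters,
#' seed, package version) is written next to each stage output.
#'
#' @param config a named list (or path to a YAML file) with `stage` and the
#'   stage parameters; a recipe is a list of such blocks under `stages`.
#' @return invisibly, a list of stage outputs; stops with a descriptive
#'   error before any computation when inputs are missing.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.null(config$stages))
    return(invisible(lapply(config$stages, run_pipeline)))
  stage <- config$stage
  if (is.null(stage)) stop("config must name a stage")
  pars <- config
  need <- function(keys) {
    miss <- setdiff(keys, names(pars))
    if (length(miss)) stop("missing config keys: ", paste(miss, collapse = ", "))
  }
  get_or <- function(key, default) if (is.null(pars[[key]])) default else pars[[key]]
  out <- switch(
    stage,
    "simulate-hopfield" = {
      need(c("n", "p", "beta", "output"))
      seed <- get_or("seed", 1L)
      pat <- generate_patterns(pars$n, pars$p, seed = seed)
      J <- hebbian_matrix(pat)
      cfg <- mc_config(pars$beta, steps = get_or("steps", 20000L),
                       burn_in = get_or("burn_in", 1000L), seed = seed)
      series <- simulate_mc(J, cfg)
      write_state_series(series, pars$output)
      if (!is.null(pars$patterns_output))
        write_matrix_tsv(pat, pars$patterns_output, list(kind = "patterns"))
      list(series = pars$output)
    },
    "cluster" = {
      need(c("input", "output"))
      if (!file.exists(pars$input)) stop("missing input: ", pars$input)
      series <- read_state_series(pars$input)
      params <- meanshift_params(n0 = get_or("n0", 10L),
                                 refine_radius = get_or("refine_radius", 2),
                                 mass_cutoff = get_or("cutoff", 0.01),
                                 seed = get_or("seed", 1L))
      res <- cluster_states(series, params)
      write_clusters(res, pars$output)
      list(clusters = pars$output)
    },
    "infer" = {
      need(c("input", "mode", "output"))
      if (!file.exists(pars$input)) stop("missing input: ", pars$input)
      series <- read_state_series(pars$input)
      fit <- if (pars$mode == "full") {
        infer_full(series)
      } else {
        need("clusters")
        if (!file.exists(pars$clusters)) stop("missing input: ", pars$clusters)
        infer_reduced(series, read_clusters(pars$clusters))
      }
      obj <- list(parametrization = fit$parametrization,
                  weights = fit$weights, J = fit$J,
                  objective = fit$objective, converged = fit$converged)
      jsonlite::write_json(obj, pars$output, auto_unbox = TRUE, digits = NA)
      list(fit = pars$output)
    },
    "symdyn" = {
      need(c("series", "clusters", "output"))
      for (f in c(pars$series, pars$clusters))
        if (!file.exists(f)) stop("missing input: ", f)
      series <- read_state_series(pars$series)
      clus <- read_clusters(pars$clusters)
      lab <- remove_self_transitions(label_series(series, clus))
      rc <- relative_complexity(lab,
                                n_surrogates = get_or("surrogates", 10),
                                seed = get_or("seed", 1L))
      obj <- list(S_LZ = rc$S_LZ, C_LZ = rc$C_LZ, R = rc$R,
                  surrogate_C = rc$surrogate_C,
                  alphabet = attr(lab, "alphabet_size"),
                  length = length(lab))
      jsonlite::write_json(obj, pars$output, auto_unbox = TRUE, digits = NA)
      list(report = pars$output)
    },
    "simulate-spiking" = {
      need(c("duration", "output"))
      seed <- get_or("seed", 1L)
      arch_keys <- intersect(names(pars), names(formals(module_architecture)))
      arch <- do.call(module_architecture, pars[arch_keys])
      inter <- NULL
      if (!is.null(pars$inter_j)) {
        if (!file.exists(pars$inter_j)) stop("missing input: ", pars$inter_j)
        inter <- read_matrix_tsv(pars$inter_j)
      }
      net <- build_spiking_network(arch, inter_j = inter, seed = seed)
      sim <- simulate_spiking(net, duration = pars$duration,
                              seed = seed + 1L, record_raster = TRUE)
      write_raster(sim$raster, pars$output)
      jsonlite::write_json(
        list(n_modules = arch$n_modules, n_e = arch$n_e, n_i = arch$n_i,
             ordering = "module-major; excitatory neurons first"),
        paste0(pars$output, ".idmap.json"), auto_unbox = TRUE)
      if (!is.null(pars$words_output)) {
        words <- binarize(module_rates(sim), theta_bin = arch$theta_bin)
        write_state_series(words, pars$words_output)
      }
      list(raster = pars$output)
    },
    "learn-correlations" = {
      need(c("targets", "iters", "output"))
      if (!file.exists(pars$targets)) stop("missing input: ", pars$targets)
      tser <- read_state_series(pars$targets)
      targets <- target_statistics(tser)
      arch_keys <- intersect(names(pars), names(formals(module_architecture)))
      arch <- do.call(module_architecture,
                      c(pars[arch_keys],
                        if (is.null(pars$n_modules))
                          list(n_modules = ncol(tser)) else NULL))
      res <- learn_correlations(arch, targets, n_iterations = pars$iters,
                                duration = get_or("duration", 100e3),
                                seed = get_or("seed", 1L))
      obj <- list(trajectory = res$trajectory, J = res$state$J,
                  nu_ext = res$state$nu_ext, failed = res$failed)
      jsonlite::write_json(obj, pars$output, auto_unbox = TRUE, digits = NA,
                           dataframe = "columns")
      list(learning = pars$output)
    },
    "fixtures" = {
      need(c("generator", "output"))
      seed <- get_or("seed", 1L)
      fx <- switch(pars$generator,
        "planted-clusters" = fixture_planted_clusters(
          n_patterns = get_or("n_patterns", 2), n = get_or("n", 50),
          copies = get_or("copies", 100),
          flip_prob = get_or("flip_prob", 0.05), seed = seed)$series,
        "small-ising" = {
          J <- hebbian_matrix(generate_patterns(get_or("n", 4),
                                                get_or("p", 1), seed))
          fixture_small_ising(J, beta = get_or("beta", 1),
                              n_samples = get_or("n_samples", 1000),
                              seed = seed)$series
        },
        "markov-chain" = NULL,
        stop("unknown generator: ", pars$generator))
      if (pars$generator == "markov-chain") {
        P <- matrix(c(0, 1, 1, 0), 2, 2)
        seqs <- fixture_markov_chain(0.5 * P + 0.25, # lazy 2-state chain
                                     length = get_or("length", 10000),
                                     seed = seed)
        write_labels(seqs, pars$output)
      } else {
        write_state_series(fx, pars$output)
      }
      list(fixture = pars$output)
    },
    stop("unknown stage: ", stage))
  prov <- list(stage = stage, params = pars,
               package = as.character(utils::packageVersion("neurolandscape")),
               time = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(prov, paste0(pars$output, ".prov.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out)
}
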