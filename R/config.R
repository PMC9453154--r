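# Configuration loading/validation and artifact management.

#' Default run configuration
#'
#' The full nested configuration of a run. Network and simulation settings
#' carry their conventional values: the `c32k8-c64k4-c64k3` conv stack with
#' strides 4, 2, 1 on a 4x84x84 frame stack, 512 hidden neurons, `T = 16`
#' simulation steps, Adam; LIF constants `tau = 2`, `v_th = 0.5`,
#' `v_reset = 0`; pbLN in conv layers with `eps = 1e-5`.
#'
#' @return Nested list of class `"run_config"`.
#' @export
default_run_config <- function() {
  structure(list(
    network = list(arch = "c32k8-c64k4-c64k3", strides = c(4L, 2L, 1L),
                   fc = 512L, pbln = TRUE, pbln_fc = FALSE,
                   pbln_per_step = FALSE, eps = 1e-5,
                   init = "uniform", weight_sd = 0.05),
    lif = list(tau = 2, v_th = 0.5, v_reset = 0),
    surrogate = list(tau_s = 2, centered = TRUE),
    train = list(T = 16L, gamma = 0.99, lr = 1e-4, batch_size = 32L,
                 buffer_capacity = 1e5, target_sync = 1000L,
                 eps_start = 1.0, eps_end = 0.05, eps_decay_steps = 1e4,
                 total_steps = 2e4, train_every = 4L, warmup = 500L,
                 frame_stack = 4L, clip_rewards = TRUE, grad_clip = Inf,
                 diag_every = 50L, seed = 1L),
    env = list(grid = 21L, paddle_width = 3L, render_size = 84L)
  ), class = "run_config")
}

#' Desk-scale training configuration
#'
#' The reduced problem size used for CPU training demonstrations: catch at
#' its native 21x21 rendering, a 2-frame stack, a `c8k5s2-c16k3s2` conv
#' stack with 64 hidden neurons, `T = 4`, batch 16, learning rate 1e-3. See
#' the methods vignette for the rationale behind these sizes.
#'
#' @param seed Run seed.
#' @return A `"run_config"`.
#' @export
smoke_run_config <- function(seed = 1L) {
  cfg <- default_run_config()
  cfg$network$arch <- "c8k5-c16k3"
  cfg$network$strides <- c(2L, 2L)
  cfg$network$fc <- 64L
  cfg$train$T <- 4L
  cfg$train$lr <- 1e-3
  cfg$train$batch_size <- 16L
  cfg$train$frame_stack <- 2L
  cfg$train$seed <- as.integer(seed)
  cfg$env$render_size <- 21L
  cfg
}

merge_config <- function(defaults, user, path = "") {
  for (nm in names(user)) {
    here <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(defaults))
      stop("unknown configuration key: ", here)
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      if (!is.list(user[[nm]]))
        stop("configuration key ", here, " must be a mapping")
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]], here)
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

validate_run_config <- function(cfg) {
  with(cfg, {
    if (train$T < 1) stop("train.T must be >= 1")
    if (train$gamma < 0 || train$gamma > 1) stop("train.gamma must lie in [0, 1]")
    if (any(c(train$eps_start, train$eps_end) < 0) ||
        any(c(train$eps_start, train$eps_end) > 1))
      stop("epsilon schedule must stay within [0, 1]")
    if (lif$tau < 1) stop("lif.tau must be >= 1")
    if (lif$v_th <= lif$v_reset) stop("lif.v_th must exceed lif.v_reset")
    if (network$eps <= 0) stop("network.eps must be > 0")
    if (env$paddle_width >= env$grid) stop("env.paddle_width must be < env.grid")
    if (env$render_size %% env$grid != 0)
      stop("env.render_size must be a multiple of env.grid")
    if (length(network$strides) != length(parse_arch(network$arch, network$strides)))
      stop("need one stride per conv layer")
  })
  invisible(cfg)
}

#' Load a run configuration from YAML
#'
#' Unknown keys are an error (no silent typos); omitted keys take the
#' documented defaults; cross-field invariants are validated.
#'
#' @param path YAML file; an empty file yields the full default
#'   configuration.
#' @return A validated `"run_config"`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- merge_config(default_run_config(), user)
  class(cfg) <- "run_config"
  validate_run_config(cfg)
  cfg
}

#' Save a run configuration to YAML
#'
#' `load_run_config(save_run_config(cfg, path))` round-trips losslessly.
#'
#' @param cfg A `"run_config"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Hash of a configuration
#'
#' Used to stamp output artifacts so every report is reproducible from its
#' own metadata.
#'
#' @param cfg A `"run_config"` (or any serializable list).
#' @return Hex digest string.
#' @export
config_hash <- function(cfg) {
  f <- tempfile(fileext = ".yml")
  on.exit(unlink(f))
  yaml::write_yaml(unclass(cfg), f)
  unname(tools::md5sum(f))
}

run_metadata <- function(cfg, seed) {
  list(config_hash = config_hash(cfg), seed = seed,
       package_version = as.character(utils::packageVersion("sdqn")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

#' Build the network and environment described by a configuration
#'
#' @param cfg A `"run_config"`.
#' @param seed Optional seed overriding `cfg$train$seed` for weight init.
#' @return List with `net` and `env`.
#' @export
config_build <- function(cfg, seed = NULL) {
  env <- catch_env(grid = cfg$env$grid, paddle_width = cfg$env$paddle_width,
                   render_size = cfg$env$render_size)
  lif <- lif_params(cfg$lif$tau, cfg$lif$v_th, cfg$lif$v_reset)
  net <- sdqn_network(
    input_shape = c(cfg$train$frame_stack, cfg$env$render_size,
                    cfg$env$render_size),
    n_actions = env$n_actions,
    conv = parse_arch(cfg$network$arch, cfg$network$strides),
    fc = cfg$network$fc, lif = lif, T = cfg$train$T,
    tau_s = cfg$surrogate$tau_s, pbln = cfg$network$pbln,
    pbln_fc = cfg$network$pbln_fc, pbln_per_step = cfg$network$pbln_per_step,
    eps = cfg$network$eps, init = cfg$network$init,
    weight_sd = cfg$network$weight_sd,
    centered_surrogate = cfg$surrogate$centered,
    seed = if (is.null(seed)) cfg$train$seed else seed)
  list(net = net, env = env)
}

train_config_from_run <- function(cfg) {
  do.call(train_config, cfg$train)
}

#' Save / load a network checkpoint
#'
#' The checkpoint container holds all weight arrays, pbLN parameters, LIF
#' constants and a format-version tag, plus run metadata.
#'
#' @param net An [sdqn_network()].
#' @param path Output path.
#' @param metadata Optional metadata list (config hash, seed, ...).
#' @return `path` (save) or the network (load).
#' @export
save_checkpoint <- function(net, path, metadata = NULL) {
  stopifnot(inherits(net, "sdqn_network"))
  saveRDS(list(format_version = net$format_version, net = net,
               metadata = metadata), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (is.null(obj$format_version) || !inherits(obj$net, "sdqn_network"))
    stop("not an sdqn checkpoint: ", path)
  obj$net
}
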