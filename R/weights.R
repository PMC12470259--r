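# Layer enumeration shared by initialization, parameter counting and the
# per-layer table, so the three can never drift apart.

layer_specs <- function(config) {
  cs <- config$channel_schedule
  L <- config$depth
  specs <- list()
  cin <- config$input_channels
  for (l in seq_len(L)) {
    specs[[length(specs) + 1L]] <-
      list(name = sprintf("enc%d.c1", l), type = "conv", k = 3L,
           cin = cin, cout = cs[l])
    specs[[length(specs) + 1L]] <-
      list(name = sprintf("enc%d.c2", l), type = "conv", k = 3L,
           cin = cs[l], cout = cs[l])
    cin <- cs[l]
  }
  if (config$sa_enabled) {
    specs[[length(specs) + 1L]] <-
      list(name = "sa", type = "conv", k = config$sa_kernel,
           cin = 2L, cout = 1L)
  }
  for (l in seq_len(L - 1L)) {
    cin <- cs[L - l + 1L]   # incoming decoder channels
    cout <- cs[L - l]       # channels at this decoder level
    transp <- config$upsample_mode == "transposed_conv"
    specs[[length(specs) + 1L]] <-
      list(name = sprintf("dec%d.up", l),
           type = if (transp) "convT" else "conv",
           k = if (transp) 2L else 1L, cin = cin, cout = cout)
    specs[[length(specs) + 1L]] <-
      list(name = sprintf("dec%d.c1", l), type = "conv", k = 3L,
           cin = 2L * cout, cout = cout)
    specs[[length(specs) + 1L]] <-
      list(name = sprintf("dec%d.c2", l), type = "conv", k = 3L,
           cin = cout, cout = cout)
  }
  if (config$isa_enabled) {
    specs[[length(specs) + 1L]] <-
      list(name = "isa", type = "conv", k = 3L, cin = 2L, cout = 1L)
  }
  specs[[length(specs) + 1L]] <-
    list(name = "head", type = "conv", k = 1L,
         cin = cs[1], cout = 1L)
  specs
}

#' Count trainable parameters
#'
#' Total number of trainable scalars (convolution weights and biases) in a
#' given configuration. The reference dual-attention configuration (five
#' levels of width 32 doubling to 512, 3x3 SA kernel, ISA enabled, 1x1
#' sigmoid head) has 7,759,559 parameters, i.e. about 7.76 M.
#'
#' @param config A [unet_config()].
#' @return Integer parameter count.
#' @examples
#' count_parameters(unet_config()) / 1e6
#' @export
count_parameters <- function(config) {
  sum(vapply(layer_specs(config),
             function(s) s$k * s$k * s$cin * s$cout + s$cout, numeric(1)))
}

#' Per-layer parameter table
#'
#' @param config A [unet_config()].
#' @return A tibble with one row per convolutional layer: `layer`, `type`,
#'   `kernel`, `in_channels`, `out_channels`, `params`.
#' @export
parameter_table <- function(config) {
  specs <- layer_specs(config)
  tibble::tibble(
    layer = vapply(specs, `[[`, character(1), "name"),
    type = vapply(specs, `[[`, character(1), "type"),
    kernel = vapply(specs, `[[`, integer(1), "k"),
    in_channels = vapply(specs, `[[`, integer(1), "cin"),
    out_channels = vapply(specs, `[[`, integer(1), "cout"),
    params = vapply(specs, function(s) s$k * s$k * s$cin * s$cout + s$cout,
                    numeric(1))
  )
}

# He-uniform initialization (limit sqrt(6 / fan_in)), zero biases; the
# caller controls the RNG state (build_model seeds it from config$seed).
init_weights <- function(config) {
  wts <- list()
  for (s in layer_specs(config)) {
    fan_in <- s$k * s$k * s$cin
    lim <- sqrt(6 / fan_in)
    wts[[paste0(s$name, ".W")]] <-
      array(runif(s$k * s$k * s$cin * s$cout, -lim, lim),
            dim = c(s$k, s$k, s$cin, s$cout))
    wts[[paste0(s$name, ".b")]] <- numeric(s$cout)
  }
  wts
}

#' Build a model
#'
#' Instantiates a network from a configuration, initializing all convolution
#' weights He-uniform (zero biases) under the configuration's seed, so two
#' builds from the same configuration are bit-identical.
#'
#' @param config A [unet_config()].
#' @return An object of class `attunet_model`: a list with `config` and
#'   `weights` (flat named list of parameter arrays).
#' @export
build_model <- function(config) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  structure(list(config = config, weights = init_weights(config)),
            class = "attunet_model")
}

#' @export
print.attunet_model <- function(x, ...) {
  cat("<attunet_model> ")
  cat(sprintf("%d parameters (%.3f M)\n",
              count_parameters(x$config),
              count_parameters(x$config) / 1e6))
  print(x$config)
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is an RDS file holding the flat weight list, with a YAML
#' sidecar (`<path>.yaml`) recording the full configuration so a checkpoint
#' is self-describing.
#'
#' @param model An `attunet_model`.
#' @param path Checkpoint file path.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   restored `attunet_model`.
#' @export
save_model <- function(model, path) {
  saveRDS(model$weights, path)
  cfg <- model$config
  yaml::write_yaml(unclass(cfg)[setdiff(names(cfg), "channel_schedule")],
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) {
    stop("checkpoint not found: ", path, call. = FALSE)
  }
  weights <- readRDS(path)
  cfg <- yaml::read_yaml(paste0(path, ".yaml"))
  config <- do.call(unet_config, cfg)
  model <- structure(list(config = config, weights = weights),
                     class = "attunet_model")
  check_weights_match(model)
  model
}

check_weights_match <- function(model) {
  expected <- unlist(lapply(layer_specs(model$config), function(s) {
    setNames(list(c(s$k, s$k, s$cin, s$cout), s$cout),
             paste0(s$name, c(".W", ".b")))
  }), recursive = FALSE)
  if (!identical(sort(names(expected)), sort(names(model$weights)))) {
    stop("checkpoint weights do not match the configuration: expected ",
         "layers ", paste(names(expected), collapse = ", "), call. = FALSE)
  }
  for (nm in names(expected)) {
    got <- dim(model$weights[[nm]]) %||% length(model$weights[[nm]])
    if (!identical(as.integer(got), as.integer(expected[[nm]]))) {
      stop(sprintf("checkpoint layer %s has shape [%s], config expects [%s]",
                   nm, paste(got, collapse = ","),
                   paste(expected[[nm]], collapse = ",")), call. = FALSE)
    }
  }
  invisible(TRUE)
}
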