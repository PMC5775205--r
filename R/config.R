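# Configuration schema (JSON or YAML):
#   variant   : one of the lv_model variants          (required)
#   species   : list of {b, m0, d} records            (required)
#   alpha     : n x n matrix, row-major list of rows  (required for n > 1)
#   delta     : scalar, crowding/combined variants
#   epsilon   : scalar, aggregation variant
#   x0        : initial densities                     (optional)
#   horizon   : time horizon                          (optional, default 2000)
#   name, notes : free-text labels                    (optional)
# Unknown keys are rejected with their names.

config_keys <- c("variant", "species", "alpha", "delta", "epsilon", "x0",
                 "horizon", "name", "notes")

#' Read a scenario configuration file
#'
#' Parses a JSON (`.json`) or YAML (`.yml`/`.yaml`) configuration into a
#' validated scenario. The round trip [write_config()] then `read_config()`
#' is lossless at full double precision for JSON.
#'
#' @param path configuration file path.
#' @return an `"lv_scenario"` (type `simulate`).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
                json = jsonlite::fromJSON(path, simplifyVector = TRUE),
                yml = ,
                yaml = yaml::read_yaml(path),
                stop("unsupported config extension '.", ext,
                     "' (use .json, .yml or .yaml)"))
  unknown <- setdiff(names(cfg), config_keys)
  if (length(unknown))
    stop("unknown config key(s) in ", path, ": ",
         paste(unknown, collapse = ", "))
  for (k in c("variant", "species"))
    if (is.null(cfg[[k]]))
      stop("config ", path, " is missing required key '", k, "'")

  sp <- cfg$species
  if (is.data.frame(sp)) sp <- lapply(seq_len(nrow(sp)), function(i) sp[i, ])
  getf <- function(rec, f, default = NULL) {
    v <- rec[[f]]
    if (is.null(v)) {
      if (is.null(default)) stop("species record missing field '", f, "'")
      default
    } else as.numeric(v)
  }
  b <- vapply(sp, getf, numeric(1), f = "b")
  m0 <- vapply(sp, getf, numeric(1), f = "m0")
  d <- vapply(sp, getf, numeric(1), f = "d", default = 0)
  n <- length(b)

  alpha <- cfg$alpha
  if (is.null(alpha)) {
    if (n > 1) stop("config ", path, " is missing required key 'alpha'")
    alpha <- 1
  } else {
    if (is.list(alpha)) alpha <- do.call(rbind, lapply(alpha, as.numeric))
    alpha <- as.matrix(alpha)
    if (any(diag(alpha) != 1))
      stop("alpha diagonal must be exactly 1 in ", path)
  }
  spec <- lv_model(variant = cfg$variant, b = b, m0 = m0, d = d,
                   alpha = alpha,
                   delta = if (is.null(cfg$delta)) 1 else cfg$delta,
                   epsilon = cfg$epsilon, n = n)
  x0 <- if (is.null(cfg$x0)) rep(0.5, n) else as.numeric(cfg$x0)
  if (length(x0) != n) stop("x0 length disagrees with species count")
  new_scenario(name = if (is.null(cfg$name)) basename(path) else cfg$name,
               type = "simulate", spec = spec, x0 = x0,
               horizon = if (is.null(cfg$horizon)) 2000 else cfg$horizon,
               notes = if (is.null(cfg$notes)) "" else cfg$notes)
}

#' Write a scenario or model configuration
#'
#' @param x an `lv_scenario` or `lv_model`.
#' @param path output path; the extension selects JSON or YAML.
#' @return `path`, invisibly.
#' @export
write_config <- function(x, path) {
  if (inherits(x, "lv_model"))
    x <- new_scenario("config", "simulate", x, rep(0.5, x$n))
  stopifnot(inherits(x, "lv_scenario"))
  spec <- x$spec
  cfg <- list(variant = spec$variant,
              species = lapply(seq_len(spec$n), function(i)
                list(b = spec$b[i], m0 = spec$m0[i], d = spec$d[i])),
              alpha = lapply(seq_len(spec$n), function(i)
                as.numeric(spec$alpha[i, ])),
              x0 = as.numeric(x$x0), horizon = x$horizon, name = x$name,
              notes = x$notes)
  if (!is.na(spec$delta) &&
      spec$variant %in% c("crowding", "classical", "combined",
                          "nonlinear_competition"))
    cfg$delta <- spec$delta
  if (!is.na(spec$epsilon)) cfg$epsilon <- spec$epsilon
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         json = jsonlite::write_json(cfg, path, auto_unbox = TRUE,
                                     digits = NA, pretty = TRUE),
         yml = ,
         yaml = yaml::write_yaml(cfg, path, precision = 17),
         stop("unsupported config extension '.", ext, "'"))
  invisible(path)
}
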