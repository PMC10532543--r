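#' Merged run configuration with YAML round-trip
#'
#' Bundles the EM and registration configurations with I/O paths, a log
#' level and the global seed, for use by the command-line interface.  Every
#' field has a default and the object round-trips losslessly through YAML.
#'
#' @param em a \code{\link{wmggmm_config}}.
#' @param reg a \code{\link{registration_config}}.
#' @param paths named list of input/output paths.
#' @param log_level one of "quiet", "info", "debug".
#' @param seed global integer seed.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(em = wmggmm_config(), reg = registration_config(),
                       paths = list(), log_level = "info", seed = 1L) {
  structure(list(em = unclass(em), reg = unclass(reg), paths = paths,
                 log_level = log_level, seed = seed),
            class = "run_config")
}

#' @rdname run_config
#' @param cfg a \code{run_config}.
#' @param path YAML file path.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  obj <- yaml::read_yaml(path)
  cfg <- run_config()
  for (nm in names(obj)) cfg[[nm]] <- obj[[nm]]
  cfg$em <- utils::modifyList(unclass(wmggmm_config()), as.list(obj$em))
  cfg$reg <- utils::modifyList(unclass(registration_config()),
                               as.list(obj$reg))
  cfg
}
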