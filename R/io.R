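#' Write a trajectory (with provenance sidecar) and read it back
#'
#' Trajectories are written as plain tab-separated text (columns `t`,
#' `x`, `x_S`, `x_G`, `bound`) with a JSON sidecar
#' (`<stem>_params.json`) holding the parameter set, scenario and seed —
#' enough to re-run the simulation bit-identically.
#'
#' @param traj A `ratchet_trajectory`.
#' @param path Output file path for the table.
#' @return `write_trajectory()` returns `path` invisibly;
#'   `read_trajectory()` returns a `ratchet_trajectory`.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.table(as.data.frame(traj), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  p <- attr(traj, "params")
  sidecar <- list(
    params = p[setdiff(names(p), "D_nm")],
    scenario = unclass(attr(traj, "scenario")),
    seed = attr(traj, "seed"),
    persistent = attr(traj, "persistent"),
    escape_time = attr(traj, "escape_time"),
    package_version = as.character(utils::packageVersion("ftsratchet")))
  jsonlite::write_json(sidecar, sidecar_path(path), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(path)
}

sidecar_path <- function(path) {
  sub("\\.[^.]*$", "", path) |> paste0("_params.json")
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- tibble::as_tibble(utils::read.table(path, header = TRUE,
                                            sep = "\t"))
  df$bound <- as.logical(df$bound)
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    attr(df, "params") <- do.call(ratchet_params, meta$params)
    attr(df, "scenario") <- do.call(ratchet_scenario, meta$scenario)
    attr(df, "seed") <- meta$seed
    attr(df, "persistent") <- meta$persistent
  }
  class(df) <- c("ratchet_trajectory", class(df))
  df
}

write_provenance <- function(dir, subcommand, args, seed) {
  jsonlite::write_json(
    list(subcommand = subcommand, args = args, seed = seed,
         package_version =
           as.character(utils::packageVersion("ftsratchet")),
         r_version = R.version.string,
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    file.path(dir, "provenance.json"),
    auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(NULL)
}
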