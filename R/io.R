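# Snapshot and morphology export.

#' Write a simulation snapshot as CSV with a metadata header
#'
#' Dense field values prefixed by commented grid metadata (grid size,
#' degree, spacing, origin, iteration, stage).
#'
#' @param snapshot one element of `sim$snapshots`.
#' @param path output file.
#' @param field which field to write (`"phi"` or `"c_tub"`).
#' @return `path`, invisibly.
#' @export
write_snapshot <- function(snapshot, path, field = c("phi", "c_tub")) {
  field <- match.arg(field)
  hdr <- sprintf(
    "# %s | iteration %d | stage %d | nu %d | nv %d | degree %d | spacing %g | origin %g %g",
    field, snapshot$iteration, snapshot$stage, snapshot$nu, snapshot$nv,
    snapshot$degree, snapshot$spacing, snapshot$origin[1],
    snapshot$origin[2])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(snapshot[[field]], con, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export simulated neuron morphology as SWC
#'
#' One tree per neuron: the soma as the root sample and every neurite's
#' soma-to-tip path (see [extract_trace()]) as a chain of samples of
#' type 2 (axon) for the selected axon and type 3 (dendrite) otherwise.
#'
#' @param sim a `neuron_growth_sim`.
#' @param path output file; for multiple neurons a numbered file per
#'   neuron is written.
#' @return Character vector of written paths, invisibly.
#' @export
write_swc <- function(sim, path) {
  reg <- sim$registry
  centers <- .centers_lattice(sim$state, sim$grid)
  paths <- character(0)
  for (n in seq_len(nrow(centers))) {
    rows <- list()
    rows[[1]] <- sprintf("%d 1 %.3f %.3f 0 %.3f -1", 1L,
                         centers[n, 1], centers[n, 2], sim$params$r0)
    nid <- 2L
    for (k in which(reg$neuron_id == n)) {
      tr <- tryCatch(extract_trace(sim$state$phi, centers[n, ],
                                   c(reg$ix[k], reg$iy[k]),
                                   sim$params$phi_threshold),
                     error = function(e) NULL)
      if (is.null(tr)) next
      type <- if (!is.na(sim$axon) && reg$neurite_id[k] == sim$axon) 2L else 3L
      parent <- 1L
      for (p in seq_len(nrow(tr))) {
        rows[[length(rows) + 1L]] <- sprintf("%d %d %.3f %.3f 0 1.0 %d",
                                             nid, type, tr[p, 1], tr[p, 2],
                                             parent)
        parent <- nid
        nid <- nid + 1L
      }
    }
    out <- if (nrow(centers) == 1) path else
      sub("(\\.swc)?$", sprintf("_neuron%d.swc", n), path)
    writeLines(c("# SWC export", unlist(rows)), out)
    paths <- c(paths, out)
  }
  invisible(paths)
}
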