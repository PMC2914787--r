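#' Write a run's per-generation time series
#'
#' Columns `generation,population,n_clusters,diversity` (plus any extra
#' recorded columns).
#'
#' @param record A `run_record` or its `series` data.frame.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_run_series <- function(record, path) {
  series <- if (inherits(record, "run_record")) record$series else record
  write.csv(series, path, row.names = FALSE)
  invisible(path)
}

#' Write a coarse-grid snapshot
#'
#' Long-format CSV with columns `generation,row,col,value` for the coarse
#' fitness matrix; optionally followed by the interpolated lattice view
#' (`x,y,fitness`) written alongside with suffix `_sampled`.
#'
#' @param landscape A landscape.
#' @param path Output CSV path.
#' @param generation Generation stamp to record.
#' @param sampled If `TRUE`, also write the 45x45 interpolated view.
#' @return The path, invisibly.
#' @export
write_grid_snapshot <- function(landscape, path, generation = NA_integer_,
                                sampled = FALSE) {
  v <- landscape$grid$values
  df <- data.frame(generation = as.integer(generation),
                   row = as.vector(row(v)),
                   col = as.vector(col(v)),
                   value = as.vector(v))
  write.csv(df, path, row.names = FALSE)
  if (sampled) {
    sp <- sample_landscape(landscape)
    sp <- cbind(generation = as.integer(generation), sp)
    write.csv(sp, sub("(\\.csv)?$", "_sampled.csv", path), row.names = FALSE)
  }
  invisible(path)
}

#' Write an organism snapshot
#'
#' Columns `generation,id,x,y,mu,parent1,parent2,labeled`; founders have
#' empty parent fields.
#'
#' @param organisms Organism data.frame.
#' @param path Output CSV path.
#' @param generation Generation stamp.
#' @return The path, invisibly.
#' @export
write_organism_snapshot <- function(organisms, path,
                                    generation = NA_integer_) {
  df <- cbind(generation = as.integer(generation),
              organisms[, c("id", "x", "y", "mu", "parent1", "parent2",
                            "labeled")])
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read an organism snapshot
#'
#' Reads a CSV written by [write_organism_snapshot()] (or any table with at
#' least `id,x,y`; a `generation` column may carry several generations).
#'
#' @param path CSV path.
#' @return Organism data.frame (with `generation` column when present).
#' @export
read_organism_snapshot <- function(path) {
  df <- read.csv(path)
  if (!all(c("id", "x", "y") %in% names(df)))
    stop("snapshot must have columns id, x, y: ", path)
  if (is.null(df$mu)) df$mu <- NA_real_
  if (is.null(df$labeled)) df$labeled <- FALSE
  df
}

#' Write a cluster partition
#'
#' Columns `generation,id,cluster`.
#'
#' @param partition A [find_clusters()] result.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_partition <- function(partition, path) {
  df <- data.frame(generation = partition$generation,
                   id = as.integer(names(partition$assignment)),
                   cluster = unname(partition$assignment))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a sweep summary
#'
#' One row per mu with the across-replicate means and standard deviations.
#'
#' @param summary A [sweep_mu()] result.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_sweep_summary <- function(summary, path) {
  write.csv(as.data.frame(summary), path, row.names = FALSE)
  invisible(path)
}

#' Write a JSON sidecar of configuration and seed
#'
#' @param config A (nested) list of configuration values.
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_sidecar <- function(config, path) {
  strip <- function(z) if (is.list(z)) lapply(unclass(z), strip) else z
  jsonlite::write_json(strip(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Cluster every generation of a snapshot table
#'
#' Standalone measurement layer: given an organism snapshot table (possibly
#' covering several generations), recomputes mates and species clusters per
#' generation and returns the long-format partition table.
#'
#' @param snapshot data.frame with columns `id,x,y` and optionally
#'   `generation`.
#' @param extent Morphospace side length.
#' @return data.frame with columns `generation,id,cluster`.
#' @export
cluster_snapshot <- function(snapshot, extent = 45) {
  gen <- if (is.null(snapshot$generation)) rep(NA_integer_, nrow(snapshot))
         else snapshot$generation
  parts <- lapply(split(seq_len(nrow(snapshot)), gen), function(ix) {
    p <- find_clusters(snapshot[ix, , drop = FALSE],
                       generation = gen[ix[1]], extent = extent)
    data.frame(generation = gen[ix[1]],
               id = as.integer(names(p$assignment)),
               cluster = unname(p$assignment))
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}
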