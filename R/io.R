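# Plain-text interchange formats: 1 ps snapshots and result tables.

#' Write a 1 ps species snapshot
#'
#' CSV with header `event,species,x_nm,y_nm,z_nm` — the standalone input of
#' the chemical stage.
#'
#' @param m A `molecule_set` (alive molecules are written).
#' @param path Output file.
#' @param event Event id column value.
#' @export
write_snapshot <- function(m, path, event = 1L) {
  idx <- which(m$alive)
  df <- data.frame(event = event,
                   species = m$species_names[m$species[idx]],
                   x_nm = m$pos[idx, 1], y_nm = m$pos[idx, 2],
                   z_nm = m$pos[idx, 3])
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a 1 ps species snapshot
#'
#' @param path Snapshot CSV (see [write_snapshot()]).
#' @param event Which event id to load (`NULL` = all rows).
#' @param registry A `chem_registry`.
#' @param box,time_ps Passed to [molecule_set()].
#' @return A `molecule_set`.
#' @export
read_snapshot <- function(path, event = NULL, registry = default_registry(),
                          box = NULL,
                          time_ps = registry$constants$chem_t_start_ps) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("event", "species", "x_nm", "y_nm", "z_nm")
  if (!all(need %in% names(df)))
    stop("snapshot must have columns ", paste(need, collapse = ","))
  if (!is.null(event)) df <- df[df$event == event, , drop = FALSE]
  molecule_set(df$species, as.matrix(df[, c("x_nm", "y_nm", "z_nm")]),
               time_ps = time_ps, box = box, registry = registry)
}

#' Write per-event species-count time series
#'
#' CSV with header `event,t_ps,species,count`.
#'
#' @param result A `chem_result`.
#' @param path Output file.
#' @param event Event id.
#' @export
write_count_series <- function(result, path, event = 1L) {
  df <- data.frame(event = event,
                   t_ps = rep(result$time_ps, each = nrow(result$counts)),
                   species = rep(rownames(result$counts),
                                 times = length(result$time_ps)),
                   count = as.vector(result$counts))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
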