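#' Write / read per-well summary tables
#'
#' The on-disk per-well table mirrors the column layout of the screen's
#' numeric summary tables: plate number, well, role, target, siRNA, cell
#' number, relative cell number, reporter-positive (interphase) cells,
#' hit-classified cells, hit rate — plus, for the Rps2-YFP readout, the
#' nucleolar/nucleoplasmic split, and for Enp1 the cytoplasmic count and
#' absolute cytoplasmic hit rate. UTF-8 CSV with a mandatory header, "."
#' decimal separator, full-precision floats, and missing values as empty
#' fields (never 0), so a written table reads back losslessly.
#'
#' @param wells per-well data.frame
#' @param path CSV path
#' @return `read_well_table` returns the data.frame; `write_well_table`
#'   returns `path` invisibly
#' @export
write_well_table <- function(wells, path) {
  utils::write.csv(wells, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8", quote = TRUE)
  invisible(path)
}

#' @rdname write_well_table
#' @export
read_well_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                        fileEncoding = "UTF-8")
  need <- c("plate", "well", "role", "target", "sirna", "cell_number",
            "hit_rate")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("well table lacks column(s): ",
                         paste(miss, collapse = ", "))
  df
}

#' Import an externally supplied per-well summary table
#'
#' Reads a per-well table in the published numeric-summary column layout so
#' that ranking, candidate selection and hit calling can run without any
#' image or per-cell data. Flexible header matching maps common column
#' spellings (e.g. "plate number", "cell number", "relative cell number",
#' "hit rate", "YFP-positive cells"/"GFP-positive cells"/"interphase
#' cells", "nucleolar"/"nucleoplasmic") onto the package's internal schema.
#'
#' @param path CSV/TSV path (separator sniffed from the header line)
#' @param readout readout id of the table
#' @return per-well data.frame in the [compute_well_statistics()] schema
#' @export
import_supplementary_wells <- function(path, readout = "rps2") {
  hdr <- readLines(path, n = 1)
  sep <- if (grepl("\t", hdr)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  norm <- function(x) gsub("[^a-z0-9]+", "", tolower(x))
  nm <- norm(names(df))
  pick <- function(...) {
    for (cand in c(...)) {
      i <- which(nm == norm(cand))
      if (length(i)) return(df[[i[1]]])
    }
    NULL
  }
  out <- data.frame(
    plate = pick("plate", "plate number", "platenumber"),
    well = {
      w <- pick("well", "well position")
      if (is.null(w)) NA_character_ else w
    },
    role = {
      r <- pick("role")
      if (is.null(r)) "sample" else r
    },
    target = pick("target", "gene", "gene symbol"),
    sirna = pick("sirna", "siRNA", "sirna id"),
    cell_number = pick("cell_number", "cell number"),
    stringsAsFactors = FALSE
  )
  rcn <- pick("relative_cell_number", "relative cell number")
  if (!is.null(rcn)) out$relative_cell_number <- rcn
  rpi <- pick("reporter_positive_interphase", "YFP-positive cells",
              "GFP-positive cells", "interphase cells")
  if (!is.null(rpi)) out$reporter_positive_interphase <- rpi
  hc <- pick("hit_count", "hit-classified cells", "hit classified cells")
  if (!is.null(hc)) out$hit_count <- hc
  hr <- pick("hit_rate", "hit rate", "hit rate (nuc.)")
  if (is.null(hr)) stop("no hit-rate column found in ", path)
  out$hit_rate <- hr
  if (readout == "rps2") {
    no <- pick("nucleolar_count", "nucleolar")
    np <- pick("nucleoplasmic_count", "nucleoplasmic")
    if (!is.null(no)) out$nucleolar_count <- no
    if (!is.null(np)) out$nucleoplasmic_count <- np
  }
  if (readout == "enp1") {
    cy <- pick("cytoplasmic_count", "cytoplasmic")
    hrc <- pick("hit_rate_cyt", "hit rate (cyt.)")
    if (!is.null(cy)) out$cytoplasmic_count <- cy
    if (!is.null(hrc)) out$hit_rate_cyt <- hrc
  }
  out
}

#' Write per-target scores and the hit list
#'
#' `write_target_table` writes the per-target CSV (per-siRNA summary flags,
#' target rank, candidate/high-confidence flags); `write_hit_list` writes a
#' plain TSV of high-confidence hit targets with their ranks.
#'
#' @param targets per-target data.frame from [call_hits()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_target_table <- function(targets, path) {
  utils::write.csv(targets, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_target_table
#' @export
write_hit_list <- function(targets, path) {
  stopifnot("high_confidence" %in% names(targets))
  hits <- targets[targets$high_confidence, c("target", "target_rank")]
  hits <- hits[order(-hits$target_rank), ]
  utils::write.table(hits, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Assemble a run configuration
#'
#' Collects every threshold that any downstream call uses, so the persisted
#' run manifest is a complete record: no hidden defaults at call time.
#'
#' @param readout readout id
#' @param cutoff high-confidence rank cutoff (default per readout)
#' @param min_relative_cell_number growth-exclusion threshold
#' @param background_multiple reporter-positive threshold multiple
#' @param enp1_cyt_threshold absolute-rate threshold for cytoplasmic Enp1
#' @param rio2_threshold Rio2 +LMB call threshold
#' @param neg_summary candidate-filter negative-control summary
#' @param seed master seed
#' @return list of class `run_config`
#' @export
run_config <- function(readout = "rps2", cutoff = default_cutoff(readout),
                       min_relative_cell_number = 0.3,
                       background_multiple = 2,
                       enp1_cyt_threshold = 0.2, rio2_threshold = 0.2,
                       neg_summary = "top2", seed = 1L) {
  structure(list(readout = readout, cutoff = cutoff,
                 min_relative_cell_number = min_relative_cell_number,
                 background_multiple = background_multiple,
                 enp1_cyt_threshold = enp1_cyt_threshold,
                 rio2_threshold = rio2_threshold,
                 neg_summary = neg_summary, seed = as.integer(seed)),
            class = "run_config")
}

#' Write the run manifest
#'
#' JSON record of every threshold, the seed and the package version;
#' re-running a manifest reproduces all tables.
#'
#' @param config a `run_config`
#' @param path JSON path
#' @param extra optional named list merged into the manifest
#' @return `path`, invisibly
#' @export
write_run_manifest <- function(config, path, extra = list()) {
  stopifnot(inherits(config, "run_config"))
  manifest <- c(unclass(config),
                list(package_version =
                       as.character(utils::packageVersion("ribohcs"))),
                extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
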