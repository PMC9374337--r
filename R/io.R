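# Plain-text IO: localization and displacement tables (CSV/TSV), diffusion
# maps (TSV grid + JSON sidecar), cell records (JSON + CSV), and the packaged
# protein panel.

readDelim <- function(path) {
  if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE))
    read.delim(path, stringsAsFactors = FALSE)
  else read.csv(path, stringsAsFactors = FALSE)
}

checkColumns <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("schema error in '", path, "': missing required column(s) ",
         paste0('"', missing, '"', collapse = ", "))
  bad <- which(!vapply(df[required], is.numeric, logical(1)))
  if (length(bad)) {
    # report malformed rows with line numbers (header is line 1)
    col <- required[bad[1]]
    v <- suppressWarnings(as.numeric(df[[col]]))
    rows <- which(is.na(v) & !is.na(df[[col]]))
    stop("schema error in '", path, "': non-numeric values in \"", col,
         "\" at line(s) ", paste(head(rows + 1L, 5), collapse = ", "))
  }
  invisible(df)
}

#' Read a localization table
#'
#' CSV or TSV with required columns `frame`, `x_nm`, `y_nm`; extra columns
#' (e.g. `truth_id`, `cell`) are preserved. Coordinates are continuous nm
#' with the origin at the field-of-view corner.
#'
#' @param path file path (.csv, .tsv or .txt).
#' @return localization data.frame.
#' @export
readLocalizations <- function(path) {
  df <- readDelim(path)
  checkColumns(df, c("frame", "x_nm", "y_nm"), path)
  df
}

#' @rdname readLocalizations
#' @param localizations localization data.frame.
#' @export
writeLocalizations <- function(localizations, path) {
  write.csv(localizations, path, row.names = FALSE)
  invisible(path)
}

#' Read or write a displacement table
#'
#' CSV with required columns `origin_x_nm`, `origin_y_nm`, `r_nm`, `couple`;
#' endpoint columns are carried when present so round trips are lossless.
#'
#' @param path file path.
#' @return displacement data.frame.
#' @export
readDisplacements <- function(path) {
  df <- readDelim(path)
  checkColumns(df, c("origin_x_nm", "origin_y_nm", "r_nm", "couple"), path)
  df
}

#' @rdname readDisplacements
#' @param displacements displacement data.frame.
#' @export
writeDisplacements <- function(displacements, path) {
  write.csv(displacements, path, row.names = FALSE)
  invisible(path)
}

#' Write or read a diffusion map
#'
#' The map grid is written as TSV (one fitted value per pixel, NA for
#' missing) next to a JSON sidecar (`<path>.json`) holding the pixel size,
#' origin, counts grid, lag time, truncation bound and fit metadata, so the
#' object round-trips losslessly.
#'
#' @param map a [DiffusionMap-class].
#' @param path path of the TSV grid.
#' @return `readDiffusionMap` returns the reconstructed
#'   [DiffusionMap-class].
#' @export
writeDiffusionMap <- function(map, path) {
  utils::write.table(map@d, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  meta <- list(pixel_size_nm = map@pixelSize, origin_nm = map@origin,
               dt = map@dt, r_max_nm = map@rMax, complete = map@complete,
               recommended_pixel_size_nm = map@recommendedPixelSize,
               counts = map@counts, k = map@k, dim = dim(map@d))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, na = "null", matrix = "rowmajor")
  invisible(path)
}

#' @rdname writeDiffusionMap
#' @export
readDiffusionMap <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  d <- as.matrix(read.delim(path, header = FALSE))
  dimnames(d) <- NULL
  toMat <- function(m) {
    if (is.matrix(m)) return(m)
    matrix(unlist(m), nrow = meta$dim[1], byrow = TRUE)
  }
  kmat <- toMat(meta$k)
  cmat <- toMat(meta$counts)
  storage.mode(cmat) <- "integer"
  new("DiffusionMap", d = d, k = kmat, counts = cmat,
      pixelSize = meta$pixel_size_nm, origin = as.numeric(meta$origin_nm),
      dt = meta$dt, rMax = meta$r_max_nm, complete = meta$complete,
      recommendedPixelSize = meta$recommended_pixel_size_nm)
}

#' Write or read segmented cells
#'
#' Cell metadata (id, rotation angle, geometry, QC state, counts, flags) go
#' to JSON; all displacements go to one CSV with a `cell` column.
#'
#' @param cells list of [CellRecord-class] objects.
#' @param path basename; writes `<path>.json` and `<path>.csv`.
#' @return `readCells` returns the reconstructed list.
#' @export
writeCells <- function(cells, path) {
  meta <- lapply(cells, function(cell) {
    list(id = cell@id, rotation_angle = cell@rotationAngle,
         length_um = cell@length, width_um = cell@width, qc = cell@qc,
         qc_reason = cell@qcReason, n_displacements = nrow(cell@displacements),
         flags = cell@flags)
  })
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  disp <- do.call(rbind, lapply(cells, function(cell) {
    d <- cell@displacements
    d$cell <- cell@id
    d
  }))
  write.csv(disp, paste0(path, ".csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname writeCells
#' @export
readCells <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = FALSE)
  disp <- read.csv(paste0(path, ".csv"), stringsAsFactors = FALSE)
  lapply(meta, function(m) {
    d <- disp[disp$cell == m$id, setdiff(names(disp), "cell"), drop = FALSE]
    rownames(d) <- NULL
    new("CellRecord", id = as.integer(m$id),
        displacements = d, rotationAngle = as.numeric(m$rotation_angle),
        length = as.numeric(m$length_um), width = as.numeric(m$width_um),
        qc = m$qc, qcReason = m$qc_reason,
        flags = lapply(m$flags, identity))
  })
}

#' Packaged protein panel
#'
#' The 12-construct panel of mEos3.2-tagged cytoplasmic proteins with
#' measured center-region diffusion coefficients: construct id, UniProt id,
#' name, number of analyzed cells, native abundance (copies/cell),
#' loneliness, monomer molecular weight (kDa), oligomeric state, complex
#' mass (kDa), and mean/SD of the center diffusion coefficient (um^2/s).
#' Two rows are heterologous thioredoxin homologs (`TrxA2_hvo`, `TrxA_lla`);
#' the remaining 10 (9 native proteins plus free mEos3.2) form the native
#' scaling set. Convenience columns `tag_mw_kda` (25.7 for fusions, 0 for
#' free mEos3.2) and `heterologous` are added on load.
#'
#' @return data.frame with 12 rows.
#' @examples
#' panel <- loadProteinPanel()
#' subset(panel, name == "Icd")$complex_mass_kda  # 142.8
#' @export
loadProteinPanel <- function() {
  path <- system.file("extdata", "protein_panel.csv", package = "smdmr",
                      mustWork = TRUE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$tag_mw_kda <- ifelse(df$name == "mEos3.2", 0, 25.7)
  df$heterologous <- df$name %in% c("TrxA2_hvo", "TrxA_lla")
  df
}
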