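#' Write fluorescence traces as TSV
#'
#' Column 1 is time (s); one column per trace. Metadata are stored as
#' `# key=value` comment lines before the header.
#'
#' @param traces A [fluor_trace()] or list of traces with identical length
#'   and `dt`.
#' @param path Output file.
#' @param metadata Named list of scalar metadata (e.g. `dt`, `seed`,
#'   `concentration`); `dt` is added automatically.
#' @return `path`, invisibly.
#' @export
write_trace_tsv <- function(traces, path, metadata = list()) {
  if (inherits(traces, "fluor_trace")) traces <- list(traces)
  n <- vapply(traces, function(t) length(t$values), 1L)
  if (length(unique(n)) != 1L) stop("traces have mismatched lengths")
  metadata$dt <- traces[[1L]]$dt
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(metadata))
    writeLines(sprintf("# %s=%s", k, format(metadata[[k]], digits = 15)), con)
  df <- data.frame(time = trace_times(traces[[1L]]))
  for (i in seq_along(traces)) df[[paste0("trace", i)]] <- traces[[i]]$values
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read fluorescence traces from TSV
#'
#' @param path File written by [write_trace_tsv()] (or any TSV whose first
#'   column is time in seconds with a constant step).
#' @return A list of [fluor_trace()] objects; parsed `# key=value` metadata
#'   are attached as attribute `metadata`.
#' @export
read_trace_tsv <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  metadata <- list()
  for (ml in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", ml), "=", fixed = TRUE)[[1L]]
    if (length(kv) == 2L) {
      v <- suppressWarnings(as.numeric(kv[2L]))
      metadata[[trimws(kv[1L])]] <- if (is.na(v)) trimws(kv[2L]) else v
    }
  }
  df <- utils::read.table(text = lines, header = TRUE, sep = "\t",
                          comment.char = "#")
  if (ncol(df) < 2L) stop("no trace columns found")
  dt <- if (!is.null(metadata$dt)) metadata$dt else stats::median(diff(df[[1L]]))
  traces <- lapply(df[-1L], fluor_trace, dt = dt, t0 = df[[1L]][1L])
  attr(traces, "metadata") <- metadata
  traces
}

#' Write an idealization as TSV
#'
#' Columns: `time` (s), `level` (0/1), `dwell_id` (running index of the
#' dwell each sample belongs to).
#'
#' @param idealized An `idealized_trace` from [idealize()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_idealization_tsv <- function(idealized, path) {
  stopifnot(inherits(idealized, "idealized_trace"))
  n <- length(idealized$levels)
  dwell_id <- rep(seq_len(nrow(idealized$dwells)),
                  idealized$dwells$n_samples)
  df <- data.frame(time = (seq_len(n) - 1L) * idealized$dt,
                   level = idealized$levels, dwell_id = dwell_id)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a fit summary as JSON
#'
#' Serialises the scalar and vector components of a fit object
#' (`autocorr_decay`, `dose_response` or `gv_fit`) to pretty-printed JSON.
#'
#' @param fit A fit object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  keep <- Filter(function(x) is.numeric(x) || is.character(x) || is.logical(x),
                 unclass(fit))
  jsonlite::write_json(keep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a concentration-response table
#'
#' @param path CSV with columns `concentration_uM`, `response` and optional
#'   `sem`, `n`.
#' @return Data frame with those columns.
#' @export
read_dose_table <- function(path) {
  df <- utils::read.csv(path)
  need <- c("concentration_uM", "response")
  if (!all(need %in% names(df)))
    stop("dose table must contain columns 'concentration_uM' and 'response'")
  df
}

#' Read a voltage-current table
#'
#' @param path CSV with columns `voltage_mV` and `current`.
#' @return Data frame with those columns.
#' @export
read_gv_table <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("voltage_mV", "current") %in% names(df)))
    stop("G-V table must contain columns 'voltage_mV' and 'current'")
  df
}

#' Write a photon-count frame stack as 16-bit multi-page TIFF
#'
#' @param stack Integer array (rows, cols, frames) with values in
#'   \[0, 65535\].
#' @param path Output TIFF file.
#' @return `path`, invisibly.
#' @export
write_frames_tiff <- function(stack, path) {
  d <- dim(stack)
  if (length(d) != 3L) stop("'stack' must be a (rows, cols, frames) array")
  if (max(stack) > 65535L || min(stack) < 0L)
    stop("counts outside the 16-bit range")
  pages <- lapply(seq_len(d[3L]), function(f) stack[, , f] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a photon-count frame stack from 16-bit TIFF
#'
#' @param path TIFF written by [write_frames_tiff()].
#' @return Integer array (rows, cols, frames).
#' @export
read_frames_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- vapply(pages, function(p) round(p * 65535),
                matrix(0, nrow(pages[[1L]]), ncol(pages[[1L]])))
  storage.mode(arr) <- "integer"
  arr
}

#' Write a pore system as multi-model PDB
#'
#' One MODEL per frame; waters as residue HOH, side-chain groups keep their
#' chain IDs. The per-atom vdW radius is stored in the B-factor column so a
#' round trip preserves it.
#'
#' @param system A [pore_system()].
#' @param path Output PDB file.
#' @return `path`, invisibly.
#' @export
write_pore_pdb <- function(system, path) {
  stopifnot(inherits(system, "pore_system"))
  at <- system$atoms
  n <- nrow(at)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("REMARK   1 STATE %s",
                     ifelse(is.na(system$state), "NA", system$state)), con)
  for (f in seq_along(system$frames)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- system$frames[[f]]
    recs <- sprintf(
      "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
      seq_len(n) %% 100000L, at$atom, at$resname, at$chain,
      at$resid %% 10000L, xyz[, 1L], xyz[, 2L], xyz[, 3L],
      1.00, system$vdw_radii)
    writeLines(recs, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-model PDB as a pore system
#'
#' Parses coordinates with `bio3d::read.pdb()` (all models); vdW radii are
#' taken from the B-factor column when positive, otherwise from
#' `default_radius`.
#'
#' @param path PDB file.
#' @param axis_origin,axis_direction Pore axis (defaults: origin at 0, axis
#'   along z).
#' @param default_radius Radius (Angstrom) for atoms without a stored one.
#' @return A [pore_system()].
#' @export
read_pore_pdb <- function(path, axis_origin = c(0, 0, 0),
                          axis_direction = c(0, 0, 1), default_radius = 1.5) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  a <- pdb$atom
  xyz <- pdb$xyz
  nf <- nrow(xyz)
  frames <- lapply(seq_len(nf), function(f)
    matrix(xyz[f, ], ncol = 3L, byrow = TRUE))
  radii <- ifelse(!is.na(a$b) & a$b > 0, a$b, default_radius)
  state <- NA_character_
  hdr <- grep("^REMARK   1 STATE", readLines(path, n = 5L), value = TRUE)
  if (length(hdr)) state <- trimws(sub("^REMARK   1 STATE", "", hdr[1L]))
  pore_system(frames,
              data.frame(resname = a$resid, resid = a$resno,
                         atom = a$elety, chain = a$chain),
              radii, axis_origin, axis_direction, state)
}
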