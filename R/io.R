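# Extended-XYZ trajectory reader/writer, columnar label tables, and the
# JSON run-configuration loader. Coordinates are reduced units end to end.

#' Read an extended-XYZ trajectory
#'
#' Standard dialect: per frame an atom-count line, a comment line carrying
#' a `Lattice="ax ay az bx by bz cx cy cz"` box specification, then one
#' `element x y z` row per particle. Element labels are tolerated and
#' ignored (particles are indistinguishable); only orthorhombic lattices
#' are accepted.
#'
#' @param path file path.
#' @return list of [configuration()] objects (frame ids 0, 1, ...).
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L; fid <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1)
      stop(sprintf("frame %d: malformed atom count line %d", fid, i))
    if (i + 1L + n > length(lines))
      stop(sprintf("frame %d: atom count mismatch (file truncated)", fid))
    comment <- lines[i + 1L]
    m <- regmatches(comment,
                    regexpr('Lattice="[^"]*"', comment, ignore.case = TRUE))
    if (length(m) == 0)
      stop(sprintf("frame %d: missing Lattice box specification", fid))
    vals <- as.numeric(strsplit(gsub('^[Ll]attice="|"$', "", m), "\\s+")[[1]])
    vals <- vals[!is.na(vals)]
    if (length(vals) != 9) stop(sprintf("frame %d: Lattice needs 9 numbers", fid))
    Lm <- matrix(vals, 3, 3, byrow = TRUE)
    if (max(abs(Lm - diag(diag(Lm)))) > 1e-10)
      stop(sprintf("frame %d: only orthorhombic boxes are supported", fid))
    rows <- lines[(i + 2L):(i + 1L + n)]
    toks <- strsplit(trimws(rows), "\\s+")
    bad <- which(vapply(toks, length, 0L) < 4)
    if (length(bad))
      stop(sprintf("frame %d: malformed coordinate row %d", fid, bad[1]))
    X <- t(vapply(toks, function(tk) as.numeric(tk[2:4]), numeric(3)))
    if (any(!is.finite(X)))
      stop(sprintf("frame %d: non-numeric coordinates", fid))
    frames[[fid + 1L]] <- configuration(X, box(diag(Lm)), id = fid)
    fid <- fid + 1L
    i <- i + 2L + n
  }
  if (length(frames) == 0) stop("no frames in file")
  frames
}

#' Write an extended-XYZ trajectory
#'
#' @param frames list of [configuration()] objects (or a single one).
#' @param path destination file.
#' @param element element label written per row (cosmetic).
#' @param digits coordinate precision.
#' @export
write_xyz <- function(frames, path, element = "X", digits = 10L) {
  if (inherits(frames, "configuration")) frames <- list(frames)
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- sprintf("%%s %%.%dg %%.%dg %%.%dg", digits, digits, digits)
  for (cf in frames) {
    L <- cf$box$lengths
    writeLines(as.character(nrow(cf$positions)), con)
    writeLines(sprintf(
      'Lattice="%.10g 0 0 0 %.10g 0 0 0 %.10g" Properties=species:S:1:pos:R:3',
      L[1], L[2], L[3]), con)
    writeLines(sprintf(fmt, element, cf$positions[, 1], cf$positions[, 2],
                       cf$positions[, 3]), con)
  }
  invisible(path)
}

#' Write a CV label table
#'
#' Whitespace-delimited columnar text with '#'-prefixed header lines
#' echoing the switching-parameter provenance.
#'
#' @param tab data.frame (e.g. columns frame, n, nQ6, nQ6_cbrt).
#' @param path destination file.
#' @param provenance named list echoed into the header.
#' @export
write_label_table <- function(tab, path, provenance = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(provenance))
    writeLines(sprintf("# %s: %s", nm,
                       paste(format(provenance[[nm]]), collapse = " ")), con)
  writeLines(paste("#", paste(names(tab), collapse = " ")), con)
  utils::write.table(format(tab, digits = 10, trim = TRUE), con,
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a columnar label table written by [write_label_table()]
#' @param path file path.
#' @return data.frame with the named columns.
#' @export
read_label_table <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  if (!length(hdr)) stop("label table has no header")
  cols <- strsplit(sub("^#\\s*", "", hdr[length(hdr)]), "\\s+")[[1]]
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(trimws(body))]
  tab <- utils::read.table(text = body, col.names = cols)
  tab
}

# -- run configuration -------------------------------------------------------

.runconfig_defaults <- function() {
  list(
    geometry = list(cutoff = NA_real_, q6_cutoff = NA_real_),
    switching = list(d0 = 0, r0 = 1.3, l = 6, m = 12,
                     sigma_q6 = 0.5, sigma_coord = 5),
    model = list(latent_dim = 8, n_layers = 2, out_dim = 1, seed = 1),
    training = list(learning_rate = 1e-3, epochs = 100, batch_size = 16,
                    split = 0.8, n_aug_rot = 0, n_aug_perm = 0, seed = 1,
                    target_transform = "cube_root", patience = 20),
    simulation = list(timestep = 0.005, temperature = 0.5, friction = 1,
                      n_steps = 1000, seed = 1),
    bias = list(kind = "pull", kappa = 0.5, center_start = 0, center_end = 1,
                w = 0.1, sigma_g = 0.1, pace = 500, gamma = Inf))
}

#' Load a run configuration
#'
#' JSON file with (subsets of) the sections geometry, switching, model,
#' training, simulation, bias; unknown sections or keys are rejected so
#' typos cannot silently fall back to defaults. Missing keys take the
#' documented defaults.
#'
#' @param path JSON file, or NULL for pure defaults.
#' @return nested list of class `run_config`.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- .runconfig_defaults()
  if (!is.null(path)) {
    user <- jsonlite::read_json(path, simplifyVector = TRUE)
    bad <- setdiff(names(user), names(cfg))
    if (length(bad)) stop("unknown config section(s): ", paste(bad, collapse = ", "))
    for (sec in names(user)) {
      badk <- setdiff(names(user[[sec]]), names(cfg[[sec]]))
      if (length(badk))
        stop(sprintf("unknown key(s) in [%s]: %s", sec,
                     paste(badk, collapse = ", ")))
      cfg[[sec]][names(user[[sec]])] <- user[[sec]]
    }
  }
  structure(cfg, class = "run_config")
}

#' Echo a run configuration as header lines
#' @param cfg a `run_config`.
#' @return character vector of "# section.key: value" lines.
#' @export
config_echo <- function(cfg) {
  unlist(lapply(names(cfg), function(sec)
    vapply(names(cfg[[sec]]), function(k)
      sprintf("# %s.%s: %s", sec, k,
              paste(format(cfg[[sec]][[k]]), collapse = " ")), "")))
}
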