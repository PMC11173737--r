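## File formats: XYZ frames, PDB waters, umbrella-window TSV, PMF TSV,
## structured run configuration.

#' Write water frames to an XYZ file
#'
#' Standard multi-frame XYZ: atom count, a comment line carrying
#' `key=value` metadata (frame index, box, any extras), then one `O`/`H`
#' line per atom in O, H, H molecule order.
#'
#' @param frames a [water_frame()] or list of them.
#' @param path output file.
#' @param metadata optional named character vector merged into every
#'   frame's comment line.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(frames, path, metadata = NULL) {
  if (inherits(frames, "water_frame")) frames <- list(frames)
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    n <- .n_waters(fr)
    meta <- c(frame = as.character(fr$frame_index), metadata)
    if (!is.null(fr$box))
      meta <- c(meta, box = paste(fr$box, collapse = ","))
    writeLines(as.character(3L * n), con)
    writeLines(paste(names(meta), meta, sep = "=", collapse = " "), con)
    if (n > 0) {
      atoms <- character(3L * n)
      fmt <- "%s %.6f %.6f %.6f"
      for (i in seq_len(n)) {
        k <- 3L * (i - 1L)
        atoms[k + 1L] <- sprintf(fmt, "O", fr$oxygen[i, 1], fr$oxygen[i, 2],
                                 fr$oxygen[i, 3])
        atoms[k + 2L] <- sprintf(fmt, "H", fr$hydrogen[i, 1, 1],
                                 fr$hydrogen[i, 1, 2], fr$hydrogen[i, 1, 3])
        atoms[k + 3L] <- sprintf(fmt, "H", fr$hydrogen[i, 2, 1],
                                 fr$hydrogen[i, 2, 2], fr$hydrogen[i, 2, 3])
      }
      writeLines(atoms, con)
    }
  }
  invisible(path)
}

#' Read water frames from an XYZ file
#'
#' Expects waters in O, H, H atom order per molecule (the order
#' [write_xyz()] emits). Box lengths are recovered from a `box=a,b,c`
#' token on the comment line when present.
#'
#' @param path XYZ file.
#' @return list of [water_frame()]s.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  pos <- 1L
  fidx <- 0L
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos]))) { pos <- pos + 1L; next }
    natoms <- as.integer(trimws(lines[pos]))
    if (is.na(natoms)) .stop_domain("malformed XYZ: bad atom count at line ", pos)
    comment <- lines[pos + 1L]
    fidx <- fidx + 1L
    box <- NULL
    frame_index <- fidx
    for (tok in strsplit(trimws(comment), "\\s+")[[1]]) {
      kv <- strsplit(tok, "=", fixed = TRUE)[[1]]
      if (length(kv) == 2 && kv[1] == "box")
        box <- as.numeric(strsplit(kv[2], ",")[[1]])
      if (length(kv) == 2 && kv[1] == "frame")
        frame_index <- as.integer(kv[2])
    }
    body <- lines[pos + 1L + seq_len(natoms)]
    pos <- pos + 2L + natoms
    if (natoms %% 3 != 0)
      .stop_domain("XYZ frame does not hold 3-site waters (atoms not multiple of 3)")
    n <- natoms %/% 3L
    if (n == 0) {
      frames[[fidx]] <- water_frame(matrix(numeric(0), 0, 3),
                                    array(numeric(0), c(0, 2, 3)),
                                    box = box, frame_index = frame_index)
      next
    }
    parts <- strsplit(trimws(body), "\\s+")
    elem <- vapply(parts, `[`, character(1), 1)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    o_rows <- seq(1, natoms, by = 3)
    if (!all(elem[o_rows] == "O") || !all(elem[-o_rows] == "H"))
      .stop_domain("XYZ frame is not in O,H,H molecule order")
    hydrogen <- array(NA_real_, c(n, 2, 3))
    hydrogen[, 1, ] <- xyz[o_rows + 1L, , drop = FALSE]
    hydrogen[, 2, ] <- xyz[o_rows + 2L, , drop = FALSE]
    frames[[fidx]] <- water_frame(xyz[o_rows, , drop = FALSE], hydrogen,
                                  box = box, frame_index = frame_index)
  }
  frames
}

#' Read waters from a PDB file
#'
#' Extracts water residues (resid `HOH`, `TIP3`, `WAT`, `SOL` or `TIP`)
#' from a PDB file and assembles one [water_frame()], grouping atoms by
#' residue number with one oxygen and two hydrogens per residue. Requires
#' the `bio3d` package.
#'
#' @param path PDB file.
#' @param box optional orthorhombic box lengths, Angstrom.
#' @return a [water_frame()].
#' @export
read_waters_pdb <- function(path, box = NULL) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    .stop_domain("reading PDB files requires the 'bio3d' package")
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  wat <- at[at$resid %in% c("HOH", "TIP3", "WAT", "SOL", "TIP"), , drop = FALSE]
  if (nrow(wat) == 0) .stop_domain("no water residues found in ", path)
  key <- paste(wat$chain, wat$resno)
  groups <- split(seq_len(nrow(wat)), factor(key, levels = unique(key)))
  n <- length(groups)
  oxygen <- matrix(NA_real_, n, 3)
  hydrogen <- array(NA_real_, c(n, 2, 3))
  for (g in seq_len(n)) {
    rows <- wat[groups[[g]], , drop = FALSE]
    o <- rows[grepl("^O", rows$elety), , drop = FALSE]
    h <- rows[grepl("^H", rows$elety), , drop = FALSE]
    if (nrow(o) != 1 || nrow(h) != 2)
      .stop_domain("water residue without exactly O,H,H atoms: ",
                   unique(paste(rows$resid, rows$resno)))
    oxygen[g, ] <- c(o$x, o$y, o$z)
    hydrogen[g, 1, ] <- c(h$x[1], h$y[1], h$z[1])
    hydrogen[g, 2, ] <- c(h$x[2], h$y[2], h$z[2])
  }
  water_frame(oxygen, hydrogen, box = box)
}

#' Write umbrella windows to TSV
#'
#' Long format, one row per sample: columns `window_id`, `center_A`,
#' `spring_k_kJ_mol_A2`, `temperature_K`, `sample_A`.
#'
#' @param windows list of [umbrella_window()]s.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_umbrella_tsv <- function(windows, path) {
  if (inherits(windows, "umbrella_window")) windows <- list(windows)
  tabs <- lapply(seq_along(windows), function(i) {
    w <- windows[[i]]
    data.frame(window_id = i, center_A = w$center,
               spring_k_kJ_mol_A2 = w$spring_k,
               temperature_K = w$temperature, sample_A = w$samples)
  })
  utils::write.table(do.call(rbind, tabs), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read umbrella windows from TSV
#'
#' Inverse of [write_umbrella_tsv()].
#'
#' @param path TSV file.
#' @return list of [umbrella_window()]s, ordered by `window_id`.
#' @export
read_umbrella_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  need <- c("window_id", "center_A", "spring_k_kJ_mol_A2", "sample_A")
  if (!all(need %in% names(df)))
    .stop_domain("umbrella TSV must have columns ",
                 paste(need, collapse = ", "))
  if (!"temperature_K" %in% names(df)) df$temperature_K <- 300
  lapply(split(df, df$window_id), function(d) {
    umbrella_window(center = d$center_A[1], spring_k = d$spring_k_kJ_mol_A2[1],
                    samples = d$sample_A, temperature = d$temperature_K[1])
  })
}

#' Write a PMF profile to TSV
#'
#' Columns `r_A`, `dG_kJ_mol`, `provenance`; masked (unsampled) bins are
#' written as `NA`.
#'
#' @param profile a `pmf_profile` (see [wham()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pmf_tsv <- function(profile, path) {
  stopifnot(inherits(profile, "pmf_profile"))
  utils::write.table(
    data.frame(r_A = profile$grid, dG_kJ_mol = profile$values,
               provenance = profile$provenance),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Read a PMF profile from TSV
#'
#' Inverse of [write_pmf_tsv()].
#'
#' @param path TSV file.
#' @return a `pmf_profile`.
#' @export
read_pmf_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!all(c("r_A", "dG_kJ_mol") %in% names(df)))
    .stop_domain("PMF TSV must have columns r_A, dG_kJ_mol")
  prov <- if ("provenance" %in% names(df)) as.character(df$provenance[1])
          else "total"
  pmf_profile(df$r_A, df$dG_kJ_mol, provenance = prov, pin = FALSE)
}

#' Emit the hydration free-energy curve as TSV
#'
#' Writes `R_A` and `dG_hydration_kJ_mol` columns over a radius grid.
#'
#' @param path output file.
#' @param R radii grid, Angstrom.
#' @param constants a [thermo_constants()] object.
#' @return `path`, invisibly.
#' @export
write_hydration_tsv <- function(path, R = seq(1, 30, by = 0.1),
                                constants = thermo_constants()) {
  utils::write.table(
    data.frame(R_A = R,
               dG_hydration_kJ_mol = hydration_free_energy(R, constants)),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
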