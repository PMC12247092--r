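# Text-table I/O: trace sets, distributions, fit reports, and coordinate
# readers (XYZ, PDB). All tables are plain delimited text; time is in
# microseconds, sigma in angular MHz, coordinates in nm unless converted.

# delimiter auto-detection among comma / tab / whitespace
detect_sep <- function(path) {
  ln <- readLines(path, n = 5L, warn = FALSE)
  ln <- ln[!grepl("^\\s*#", ln) & nzchar(trimws(ln))]
  if (any(grepl(",", ln))) "," else if (any(grepl("\t", ln))) "\t" else ""
}

#' Read an ih-RIDME trace set from text tables
#'
#' Accepts either a single wide table (first column time in microseconds,
#' one intensity column per mixing time, with a header like
#' `t,V30,V60,V120` from which the mixing times are parsed) or several
#' two-column files, one per mixing time given in `Tmix`. Delimiters
#' (comma, tab, whitespace) are auto-detected.
#'
#' @param path File path, or a vector of two-column file paths.
#' @param Tmix Mixing times for multi-file input (microseconds), or to
#'   override header parsing.
#' @param d1,d2 Static delays stored as metadata.
#' @param normalized Whether the stored traces are already normalized.
#' @return A [trace_set()].
#' @export
read_traceset <- function(path, Tmix = NULL, d1 = NA_real_, d2 = NA_real_,
                          normalized = FALSE) {
  read_one <- function(p) {
    tab <- utils::read.table(p, header = FALSE, sep = detect_sep(p),
                             comment.char = "#", strip.white = TRUE,
                             stringsAsFactors = FALSE)
    header <- NULL
    if (!is.numeric(tab[[1]])) {
      header <- as.character(unlist(tab[1, ]))
      tab <- tab[-1, , drop = FALSE]
      tab[] <- lapply(tab, function(col) as.numeric(as.character(col)))
    }
    bad <- which(!stats::complete.cases(tab))
    if (length(bad))
      stop("non-numeric or missing values in ", p, " at data row ", bad[1])
    list(tab = as.matrix(tab), header = header)
  }
  if (length(path) == 1L) {
    x <- read_one(path)
    tab <- x$tab
    if (ncol(tab) < 3 && is.null(Tmix))
      stop("single two-column file needs an explicit Tmix")
    if (is.null(Tmix)) {
      if (is.null(x$header))
        stop("missing Tmix metadata: supply Tmix or a header like t,V30,V60")
      Tmix <- as.numeric(gsub("[^0-9.]", "", x$header[-1]))
      if (any(is.na(Tmix))) stop("cannot parse mixing times from header")
    }
    trace_set(tab[, 1], tab[, -1, drop = FALSE], Tmix, d1 = d1, d2 = d2,
              normalized = normalized)
  } else {
    if (is.null(Tmix) || length(Tmix) != length(path))
      stop("one Tmix per file is required")
    xs <- lapply(path, read_one)
    t_ax <- xs[[1]]$tab[, 1]
    for (x in xs) {
      if (!isTRUE(all.equal(x$tab[, 1], t_ax)))
        stop("time axes differ between files")
    }
    traces <- vapply(xs, function(x) x$tab[, 2], numeric(length(t_ax)))
    trace_set(t_ax, traces, Tmix, d1 = d1, d2 = d2, normalized = normalized)
  }
}

#' Write a trace set as a wide CSV table
#'
#' @param ts A [trace_set()].
#' @param path Output path.
#' @export
write_traceset <- function(ts, path) {
  stopifnot(inherits(ts, "trace_set"))
  tab <- cbind(ts$time, ts$traces)
  colnames(tab) <- c("t", paste0("V", ts$Tmix))
  utils::write.table(format(tab, digits = 15, trim = TRUE, scientific = FALSE),
                     path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a sigma distribution table
#'
#' Two-column text table `sigma,p` (angular MHz); a third column gives the
#' equivalent molar proton concentration via the water-glycerol calibration.
#'
#' @param dist A [density_distribution()].
#' @param path File path.
#' @export
write_distribution <- function(dist, path) {
  stopifnot(inherits(dist, "density_distribution"))
  tab <- data.frame(sigma = dist$sigma, p = dist$p,
                    CH_molar = sigma_concentration(dist$sigma, "sigma", "molar"))
  utils::write.table(format(tab, digits = 15, trim = TRUE), path, sep = ",",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distribution
#' @export
read_distribution <- function(path) {
  tab <- utils::read.csv(path)
  density_distribution(tab$sigma, tab$p, normalize = FALSE)
}

#' Write a structured fit report
#'
#' Key-value text report of a [ridme_fit()] or [cutoff_scan()] result:
#' moments, kernel parameters, RMSD and convergence status; the fitted
#' distribution table is written next to it as `<path>.psigma.csv`.
#'
#' @param x A `ridme_fit`, `ridme_scan` or `cutoff_scan`.
#' @param path Report path.
#' @export
write_report <- function(x, path) {
  lines <- c(paste0("tool_version: ihridme ",
                    as.character(utils::packageVersion("ihridme"))),
             paste0("date: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")))
  if (inherits(x, "ridme_fit")) {
    st <- distribution_stats(x$distribution)
    lines <- c(lines,
      "result: ridme_fit",
      sprintf("kappa_per_us: %.8g", x$kappa),
      sprintf("beta: %.8g", x$beta),
      sprintf("lambda: %.8g", x$lambda),
      sprintf("mean_sigma_MHz: %.8g", st["mean"]),
      sprintf("sd_sigma_MHz: %.8g", st["sd"]),
      sprintf("skewness: %.8g", st["skewness"]),
      sprintf("mean_CH_molar: %.8g",
              sigma_concentration(st[["mean"]], "sigma", "molar")),
      sprintf("rmsd: %.8g", x$rmsd),
      sprintf("iterations: %d", x$iterations),
      sprintf("converged: %s", x$converged))
    write_distribution(x$distribution, paste0(path, ".psigma.csv"))
  } else if (inherits(x, "ridme_scan")) {
    lines <- c(lines, "result: ridme_scan",
               sprintf("kappa_opt_per_us: %.8g", x$kappa_opt),
               sprintf("beta_opt: %.8g", x$beta_opt),
               sprintf("rmsd_min: %.8g", min(x$rmsd)))
    m <- cbind(kappa = x$kappa, x$rmsd)
    utils::write.table(format(m, digits = 10, trim = TRUE),
                       paste0(path, ".rmsd.csv"),
                       sep = ",", quote = FALSE, row.names = FALSE)
  } else if (inherits(x, "cutoff_scan")) {
    st <- distribution_stats(x$prediction$distribution)
    lines <- c(lines, "result: cutoff_scan",
               sprintf("r_cut_opt_nm: %.8g", x$r_cut_opt),
               sprintf("rmsd_min: %.8g", min(x$rmsd)),
               sprintf("mean_sigma_MHz: %.8g", st["mean"]),
               sprintf("sd_sigma_MHz: %.8g", st["sd"]))
    write_distribution(x$prediction$distribution, paste0(path, ".psigma.csv"))
  } else stop("unsupported result type")
  writeLines(lines, path)
  invisible(path)
}

#' Read XYZ coordinates
#'
#' Plain XYZ: an optional atom-count/comment header, then
#' `element x y z` per line. Coordinates are returned in nm (`scale`
#' converts from the file unit; default Angstrom input).
#'
#' @param path File path.
#' @param scale Factor from file units to nm (default 0.1, Angstrom).
#' @return Data frame with `element`, `x`, `y`, `z` (nm).
#' @export
read_xyz <- function(path, scale = 0.1) {
  ln <- trimws(readLines(path, warn = FALSE))
  ln <- ln[nzchar(ln)]
  # skip count + comment header if present
  if (grepl("^[0-9]+$", ln[1])) ln <- ln[-(1:2)]
  parts <- strsplit(ln, "\\s+")
  bad <- which(vapply(parts, length, integer(1)) < 4)
  if (length(bad)) stop("malformed XYZ line ", bad[1])
  xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
  if (any(!is.finite(xyz))) stop("non-numeric coordinates in ", path)
  data.frame(element = vapply(parts, `[[`, character(1), 1),
             x = xyz[, 1] * scale, y = xyz[, 2] * scale, z = xyz[, 3] * scale)
}

#' Read a coordinate ensemble
#'
#' Builds a `ridme_ensemble` (see [ensemble_sigma()]) from XYZ files (one
#' conformer each) or a multi-model PDB. Hydrogens are selected by element;
#' the electron position is taken from a designated pseudo-atom element /
#' atom name (e.g. a named dummy atom at the N-O midpoint of a nitroxide)
#' or supplied as coordinates.
#'
#' @param paths XYZ file paths (one per conformer) or one PDB path.
#' @param electron Element symbol (XYZ) or atom name (PDB) of the
#'   electron-spot pseudo-atom, or a length-3 numeric position in nm.
#' @param format `"xyz"` or `"pdb"` (PDB requires the bio3d package).
#' @param scale XYZ unit conversion to nm (see [read_xyz()]).
#' @return A `ridme_ensemble`.
#' @export
read_ensemble <- function(paths, electron = "X", format = c("xyz", "pdb"),
                          scale = 0.1) {
  format <- match.arg(format)
  if (format == "xyz") {
    conf <- lapply(paths, function(p) {
      at <- read_xyz(p, scale = scale)
      xyz <- as.matrix(at[, c("x", "y", "z")])
      if (is.numeric(electron)) {
        e_pos <- electron
      } else {
        ei <- which(at$element == electron)
        if (length(ei) != 1L)
          stop("expected exactly one electron pseudo-atom '", electron,
               "' in ", p)
        e_pos <- xyz[ei, ]
        xyz <- xyz[-ei, , drop = FALSE]
        at <- at[-ei, , drop = FALSE]
      }
      keep <- at$element %in% c("H", "1H")
      list(electron = as.numeric(e_pos),
           protons = xyz[keep, , drop = FALSE])
    })
  } else {
    if (!requireNamespace("bio3d", quietly = TRUE))
      stop("PDB reading requires the bio3d package")
    pdb <- bio3d::read.pdb(paths[1], multi = TRUE)
    xyz_all <- pdb$xyz
    n_model <- nrow(xyz_all)
    at <- pdb$atom
    h_idx <- which(at$elesy == "H" | grepl("^H", trimws(at$elety)))
    conf <- lapply(seq_len(n_model), function(m) {
      co <- matrix(xyz_all[m, ], ncol = 3, byrow = TRUE) * 0.1  # A -> nm
      if (is.numeric(electron)) {
        e_pos <- electron
      } else {
        ei <- which(trimws(at$elety) == electron)
        if (length(ei) != 1L)
          stop("expected exactly one electron pseudo-atom '", electron, "'")
        e_pos <- co[ei, ]
      }
      list(electron = as.numeric(e_pos),
           protons = co[setdiff(h_idx, which(trimws(at$elety) == electron)),
                        , drop = FALSE])
    })
  }
  structure(conf, class = "ridme_ensemble")
}
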