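# Spot-list files and machine-readable reports. Spot lists are plain
# tab-separated text with a header row: one spot per line, detector
# coordinates in mm (absolute detector frame), intensities in any
# consistent unit, and the oscillation range of the source image per spot.

spot_columns <- c("image_id", "x_mm", "y_mm", "phi_start_deg",
                  "phi_end_deg", "intensity", "sigma")

#' Read a spot list
#'
#' @param path path to a tab-separated spot file with columns `image_id,
#'   x_mm, y_mm, phi_start_deg, phi_end_deg, intensity, sigma` and
#'   optionally `size_mm`. Unknown columns are ignored with a warning.
#' @return data frame of spots in file order.
#' @export
read_spot_list <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!nrow(df)) stop("empty spot list: ", path)
  miss <- setdiff(spot_columns, names(df))
  if (length(miss))
    stop("spot list ", path, " is missing columns: ",
         paste(miss, collapse = ", "))
  extra <- setdiff(names(df), c(spot_columns, "size_mm"))
  if (length(extra)) {
    warning("ignoring unknown columns: ", paste(extra, collapse = ", "))
    df <- df[, setdiff(names(df), extra), drop = FALSE]
  }
  num <- setdiff(names(df), "image_id")
  for (cn in num) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(is.na(v) & !is.na(df[[cn]]))
    if (length(bad))
      stop(sprintf("malformed value in column '%s' at line %d of %s",
                   cn, bad[1L] + 1L, path))
    if (anyNA(v))
      stop(sprintf("missing value in column '%s' at line %d of %s",
                   cn, which(is.na(v))[1L] + 1L, path))
    df[[cn]] <- v
  }
  validate_spots(df)
  df
}

#' Write a spot list
#'
#' @param spots spot-list data frame.
#' @param path output path. Writing then reading a file reproduces the
#'   values exactly (full-precision text).
#' @export
write_spot_list <- function(spots, path) {
  validate_spots(spots)
  df <- spots
  for (cn in setdiff(names(df), "image_id"))
    df[[cn]] <- sprintf("%.17g", df[[cn]])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

solution_report_list <- function(result) {
  st <- result$solutions
  sol <- lapply(seq_len(nrow(st)), function(i) {
    r <- st[i, ]
    list(character_id = r$id, lattice_type = r$bravais,
         penalty = r$penalty,
         cell = list(a = round(r$a, 2), b = round(r$b, 2), c = round(r$c, 2),
                     alpha = round(r$alpha, 2), beta = round(r$beta, 2),
                     gamma = round(r$gamma, 2)),
         sigma_xy_mm = if (is.na(r$sigma_xy_mm)) NULL else round(r$sigma_xy_mm, 3),
         sigma_phi_deg = if (is.na(r$sigma_phi_deg)) NULL else round(r$sigma_phi_deg, 3),
         delta_beam_mm = if (is.na(r$delta_beam_mm)) NULL else round(r$delta_beam_mm, 3),
         pseudo_symmetry_suspect = r$pseudo_symmetry_suspect,
         highlighted = r$highlighted)
  })
  list(n_spots = result$diagnostics$n_spots,
       rejection_fraction = round(result$diagnostics$rejection_fraction, 4),
       solutions = sol)
}

validate_report <- function(rep) {
  stopifnot(is.list(rep))
  sols <- if (!is.null(rep$lattices))
    unlist(lapply(rep$lattices, `[[`, "solutions"), recursive = FALSE)
  else rep$solutions
  stopifnot(length(sols) > 0)
  for (s in sols) {
    stopifnot(is.character(s$lattice_type), length(s$lattice_type) == 1L,
              is.numeric(s$penalty),
              all(c("a", "b", "c", "alpha", "beta", "gamma") %in% names(s$cell)),
              is.logical(s$highlighted))
  }
  invisible(rep)
}

#' Write an indexing report
#'
#' Serializes a single- or multi-lattice indexing result as JSON: one
#' solution table per lattice (lattice type, penalty, cell to 0.01,
#' residuals to 0.001, flags), plus the spot assignment and misorientation
#' angles for multi-lattice results. The report is schema-validated before
#' writing.
#'
#' @param result a `fftindex_indexing` or `fftindex_multilattice`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path) {
  rep <- if (inherits(result, "fftindex_multilattice")) {
    list(lattices = lapply(seq_along(result$lattices), function(k) {
           c(list(lattice = k,
                  misorientation_deg = round(result$misorientation_deg[k], 3),
                  n_spots_assigned = sum(result$assignment == k, na.rm = TRUE)),
             solution_report_list(result$lattices[[k]]))
         }),
         assignment = as.list(ifelse(is.na(result$assignment), -1L,
                                     result$assignment)))
  } else if (inherits(result, "fftindex_indexing")) {
    solution_report_list(result)
  } else stop("not an indexing result")
  validate_report(rep)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Format a solution table for terminal display
#'
#' @param result a `fftindex_indexing`.
#' @param max_rows rows to show (default: all refined plus the first
#'   unrefined).
#' @return character vector of lines.
#' @export
format_solution_table <- function(result, max_rows = NULL) {
  st <- result$solutions
  if (is.null(max_rows)) max_rows <- max(which(!is.na(st$sigma_xy_mm)), 1L) + 1L
  st <- utils::head(st, max_rows)
  hdr <- sprintf("%3s %4s %7s %8s %8s %8s %7s %7s %7s %9s %8s %7s %s",
                 "id", "lat", "penalty", "a", "b", "c", "alpha", "beta",
                 "gamma", "sig(x,y)", "sig(phi)", "d(beam)", "")
  lines <- vapply(seq_len(nrow(st)), function(i) {
    r <- st[i, ]
    sprintf("%3d %4s %7d %8.2f %8.2f %8.2f %7.2f %7.2f %7.2f %9s %8s %7s %s",
            r$id, r$bravais, r$penalty, r$a, r$b, r$c, r$alpha, r$beta,
            r$gamma,
            if (is.na(r$sigma_xy_mm)) "-" else sprintf("%.3f", r$sigma_xy_mm),
            if (is.na(r$sigma_phi_deg)) "-" else sprintf("%.3f", r$sigma_phi_deg),
            if (is.na(r$delta_beam_mm)) "-" else sprintf("%.3f", r$delta_beam_mm),
            paste0(if (isTRUE(r$highlighted)) "<== " else "",
                   if (isTRUE(r$pseudo_symmetry_suspect)) "(pseudo?)" else ""))
  }, "")
  c(hdr, lines)
}
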