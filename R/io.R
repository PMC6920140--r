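#' Read a peak list from an MGF file
#'
#' Minimal Mascot Generic Format reader: `BEGIN IONS`/`END IONS` blocks
#' with `TITLE`, `PEPMASS` and `CHARGE` headers honored and unknown
#' headers ignored. Peak lines are whitespace-separated m/z and intensity.
#'
#' @param path MGF file path.
#' @return A list of [mass_spectrum()] objects; each carries attributes
#'   `title`, `pepmass`, `charge` when present in the file.
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^BEGIN IONS\\s*$", lines)
  ends <- grep("^END IONS\\s*$", lines)
  if (length(starts) != length(ends) || any(ends < starts)) {
    stop("malformed MGF (unbalanced BEGIN/END IONS): ", path)
  }
  out <- vector("list", length(starts))
  for (b in seq_along(starts)) {
    block <- lines[(starts[b] + 1):(ends[b] - 1)]
    block <- trimws(block)
    block <- block[nzchar(block)]
    is_header <- grepl("^[A-Za-z]", block)
    headers <- block[is_header]
    peaks <- block[!is_header]
    kv <- strsplit(headers, "=", fixed = TRUE)
    keys <- toupper(vapply(kv, `[`, character(1), 1))
    vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), character(1))
    parsed <- lapply(strsplit(peaks, "[ \t]+"), function(x) {
      v <- suppressWarnings(as.numeric(x[1:2]))
      if (anyNA(v)) stop("unparseable peak line in ", path, ": ", paste(x, collapse = " "))
      v
    })
    mz <- vapply(parsed, `[`, numeric(1), 1)
    inten <- vapply(parsed, `[`, numeric(1), 2)
    spec <- mass_spectrum(mz, inten, source_id = basename(path))
    if ("TITLE" %in% keys) attr(spec, "title") <- vals[keys == "TITLE"][1]
    if ("PEPMASS" %in% keys) {
      attr(spec, "pepmass") <- as.numeric(strsplit(vals[keys == "PEPMASS"][1],
                                                   "[ \t]+")[[1]][1])
    }
    if ("CHARGE" %in% keys) {
      attr(spec, "charge") <- as.integer(sub("\\+$", "", vals[keys == "CHARGE"][1]))
    }
    out[[b]] <- spec
  }
  out
}

#' Write spectra to an MGF file
#'
#' @param spectra A [mass_spectrum()] or list thereof.
#' @param path Output path.
#' @export
write_mgf <- function(spectra, path) {
  if (inherits(spectra, "mass_spectrum")) spectra <- list(spectra)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(spectra)) {
    s <- spectra[[i]]
    writeLines("BEGIN IONS", con)
    title <- attr(s, "title")
    if (is.null(title)) title <- attr(s, "source_id")
    if (!is.null(title) && !is.na(title)) {
      writeLines(paste0("TITLE=", title), con)
    }
    if (!is.null(attr(s, "pepmass"))) {
      writeLines(paste0("PEPMASS=", attr(s, "pepmass")), con)
    }
    if (!is.null(attr(s, "charge"))) {
      writeLines(paste0("CHARGE=", attr(s, "charge"), "+"), con)
    }
    writeLines(sprintf("%.6f %.6f", s$mz, s$intensity), con)
    writeLines("END IONS", con)
  }
  invisible(path)
}

#' Read a two-column m/z, intensity CSV peak list
#'
#' Header optional; decimal separator is `.`.
#'
#' @param path CSV path.
#' @return A [mass_spectrum()].
#' @export
read_peaks_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1)
  has_header <- !grepl("^[0-9.eE+, \t-]+$", first)
  df <- utils::read.csv(path, header = has_header)
  if (ncol(df) < 2) stop("peak CSV needs 2 columns (mz, intensity): ", path)
  mass_spectrum(df[[1]], df[[2]], source_id = basename(path))
}

#' @rdname read_peaks_csv
#' @param spectrum A [mass_spectrum()] or [isotope_pattern()].
#' @export
write_peaks_csv <- function(spectrum, path) {
  df <- as.data.frame(spectrum)[, 1:2]
  names(df) <- c("mz", "intensity")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read candidate sequences from CSV or FASTA
#'
#' CSV files need columns `id` and `sequence` (optionally `provenance`);
#' FASTA records use the record name as id.
#'
#' @param path Candidate file.
#' @return Data frame with `id`, `sequence`, `provenance`.
#' @export
read_candidates <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.(fa|fasta|faa)$", path, ignore.case = TRUE)) {
    set <- Biostrings::readAAStringSet(path)
    return(data.frame(id = names(set), sequence = as.character(set),
                      provenance = NA_character_, row.names = NULL,
                      stringsAsFactors = FALSE))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("id", "sequence") %in% names(df))) {
    stop("candidate CSV needs 'id' and 'sequence' columns: ", path)
  }
  if (is.null(df$provenance)) df$provenance <- NA_character_
  df$sequence <- toupper(df$sequence)
  df[, c("id", "sequence", "provenance")]
}

#' Read a long-format aligned LC-MS feature table
#'
#' Expects columns `sample`, `feature`, `mz`, `rt`, `area` (extra columns
#' kept).
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample", "feature", "mz", "rt", "area")
  if (!all(need %in% names(df))) {
    stop("feature table needs columns ", paste(need, collapse = ", "), ": ", path)
  }
  if (anyDuplicated(df[, c("sample", "feature")])) {
    stop("duplicate (sample, feature) rows in ", path)
  }
  df
}

#' Pipeline configuration
#'
#' Central defaults for every tolerance and constant-mode choice in the
#' identification pipeline; loadable from a YAML-like `key: value` text
#' file with unknown keys rejected.
#'
#' @param precursor_tol_ppm Precursor match tolerance (default 20 ppm).
#' @param fragment_tol_ppm MS/MS match tolerance (default 10 ppm).
#' @param rt_tol Feature-alignment retention-time tolerance (default
#'   0.10 min).
#' @param mz_tol Feature-alignment mass tolerance (default 0.05 Da).
#' @param constants_mode `"modern"` or `"legacy"` hydrogen constant for
#'   cysteine corrections.
#' @param max_exons,max_gap Coding-match search limits.
#' @param seed Seed recorded for simulation steps.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(precursor_tol_ppm = 20, fragment_tol_ppm = 10,
                            rt_tol = 0.10, mz_tol = 0.05,
                            constants_mode = c("modern", "legacy"),
                            max_exons = 3L, max_gap = 50000L,
                            seed = 1L) {
  structure(list(precursor_tol_ppm = precursor_tol_ppm,
                 fragment_tol_ppm = fragment_tol_ppm,
                 rt_tol = rt_tol, mz_tol = mz_tol,
                 constants_mode = match.arg(constants_mode),
                 max_exons = as.integer(max_exons),
                 max_gap = as.integer(max_gap),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path Text file of `key: value` lines; keys must be
#'   `pipeline_config()` arguments.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, ":", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, character(1), 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = ":"), character(1)))
  known <- names(formals(pipeline_config))
  unknown <- setdiff(keys, known)
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  args <- stats::setNames(as.list(vals), keys)
  num <- setdiff(known, "constants_mode")
  args[names(args) %in% num] <- lapply(args[names(args) %in% num], as.numeric)
  do.call(pipeline_config, args)
}

#' Run the end-to-end identification pipeline
#'
#' Chains the full workflow: deconvolute the precursor charge-state
#' series to a neutral mass, filter and rank candidate sequences by
#' precursor mass and MS/MS fragment evidence, search a nucleotide
#' sequence for coding matches of the top candidate, and compute the
#' conservation report across all candidates. With no MS/MS spectrum the
#' ranking falls back to precursor evidence only (flagged in the report).
#'
#' @param precursor A [mass_spectrum()] of the intact-peptide survey scan,
#'   or a data frame of `(mz, z)` observations if charges are already
#'   known.
#' @param msms A [mass_spectrum()] of fragment ions, or `NULL`.
#' @param candidates Candidate data frame or file (see
#'   [read_candidates()]).
#' @param nuc Optional nucleotide sequence (see [translate_nuc()]) to
#'   search for coding matches of the top candidate.
#' @param config A [pipeline_config()].
#' @return A list of class `identification_report`: `inferred_mass`,
#'   `ppm_spread`, `ranking`, `top_candidate`, `any_pass`,
#'   `genomic_hits`, `conservation`, `config`.
#' @export
run_identify <- function(precursor, msms = NULL, candidates,
                         nuc = NULL, config = pipeline_config()) {
  if (is.data.frame(precursor) && all(c("mz", "z") %in% names(precursor)) &&
      !inherits(precursor, "mass_spectrum")) {
    obs <- precursor
  } else {
    spec <- .as_spectrum(precursor)
    obs <- assign_charges(spec)
    if (nrow(obs) == 0) stop("no charge-state envelopes detected in precursor spectrum")
  }
  series <- deconvolute(obs)
  ranking <- rank_candidates(candidates, series$inferred_neutral_mass,
                             msms = msms,
                             precursor_tol_ppm = config$precursor_tol_ppm,
                             fragment_tol_ppm = config$fragment_tol_ppm)
  any_pass <- any(ranking$passes_precursor)
  top <- if (any_pass) ranking$sequence[1] else NA_character_
  hits <- NULL
  if (!is.null(nuc) && any_pass) {
    hits <- find_coding_matches(top, nuc, max_exons = config$max_exons,
                                max_gap = config$max_gap)
  }
  cons <- NULL
  cand_df <- .as_candidates(candidates)
  if (nrow(cand_df) >= 2) {
    cons <- conservation(stats::setNames(cand_df$sequence, cand_df$id))
  }
  structure(list(inferred_mass = series$inferred_neutral_mass,
                 ppm_spread = series$ppm_spread,
                 ranking = ranking,
                 top_candidate = top,
                 any_pass = any_pass,
                 msms_used = isTRUE(ranking$msms_used[1]),
                 genomic_hits = hits,
                 conservation = cons,
                 config = config),
            class = "identification_report")
}

#' @export
print.identification_report <- function(x, ...) {
  cat("== identification report ==\n")
  cat(sprintf("inferred neutral mass: %.5f Da (ppm spread %.2f)\n",
              x$inferred_mass, x$ppm_spread))
  if (!x$any_pass) {
    cat("no candidate passes the precursor filter\n")
  } else {
    cat("top candidate:", x$top_candidate, "\n")
  }
  if (!x$msms_used) cat("note: no MS/MS evidence; precursor-only ranking\n")
  print(utils::head(x$ranking[, c("rank", "id", "precursor_ppm",
                                  "passes_precursor", "fragment_coverage")], 8))
  if (!is.null(x$genomic_hits)) {
    cat(length(x$genomic_hits), "genomic coding match(es)\n")
  }
  invisible(x)
}

#' Write an identification report to JSON and Markdown
#'
#' @param report A [run_identify()] result.
#' @param path_json,path_md Output paths (either may be `NULL` to skip).
#' @export
write_report <- function(report, path_json = NULL, path_md = NULL) {
  if (!is.null(path_json)) {
    hits <- if (is.null(report$genomic_hits)) list() else {
      lapply(report$genomic_hits, function(h) {
        list(seq_id = h$seq_id, strand = h$strand, frame = h$frame,
             exons = h$exons, translated = h$translated)
      })
    }
    payload <- list(
      inferred_mass = report$inferred_mass,
      ppm_spread = report$ppm_spread,
      any_pass = report$any_pass,
      top_candidate = report$top_candidate,
      msms_used = report$msms_used,
      ranking = report$ranking,
      genomic_hits = hits,
      identity_matrix = if (is.null(report$conservation)) NULL else
        report$conservation$identity_matrix,
      variant_columns = if (is.null(report$conservation)) NULL else
        report$conservation$variant_columns,
      config = unclass(report$config)
    )
    jsonlite::write_json(payload, path_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  if (!is.null(path_md)) {
    lines <- c("# Identification report", "",
               sprintf("* Inferred neutral mass: %.5f Da (ppm spread %.2f)",
                       report$inferred_mass, report$ppm_spread),
               if (report$any_pass) {
                 sprintf("* Top candidate: `%s`", report$top_candidate)
               } else {
                 "* **No candidate passes the precursor filter**"
               },
               if (!report$msms_used) "* No MS/MS evidence; precursor-only ranking",
               "", "## Candidate ranking", "",
               paste(utils::capture.output(print(report$ranking)), collapse = "\n"))
    writeLines(lines, path_md)
  }
  invisible(report)
}
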