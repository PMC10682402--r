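#' Write a per-cell division-tracking table
#'
#' Serialises a `cell_table` to tab-separated text with header columns
#' `strain`, `replicate`, `cell_id`, `divisions`, `end_state`,
#' `division_times`. On disk the end state uses the bench vocabulary
#' `dead`/`alive` (a cell alive at experiment end is censored);
#' division times are semicolon-separated minutes. Output is
#' deterministic: the same table always writes byte-identical files.
#'
#' @param cells A `cell_table` (see [simulate_experiment()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(cells, path) {
  stopifnot(is.data.frame(cells),
            all(c("strain", "replicate", "cell_id", "divisions", "end_state")
                %in% names(cells)))
  times <- if ("division_times" %in% names(cells)) {
    vapply(cells$division_times, function(t)
      paste(sprintf("%.4f", t), collapse = ";"), "")
  } else {
    rep("", nrow(cells))
  }
  df <- data.frame(strain = cells$strain, replicate = cells$replicate,
                   cell_id = cells$cell_id, divisions = cells$divisions,
                   end_state = ifelse(cells$end_state == "censored",
                                      "alive", cells$end_state),
                   division_times = times, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-cell division-tracking table
#'
#' Parses the TSV format written by [write_cell_table()] (or prepared by
#' hand from tracking software exports). `end_state` must be `dead` or
#' `alive`; `alive` is mapped to `censored` on ingest. Malformed rows
#' abort with the offending line number.
#'
#' @param path TSV file with header `strain`, `replicate`, `cell_id`,
#'   `divisions`, `end_state` and optional `division_times`.
#' @return A `cell_table` data frame.
#' @export
read_cell_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("strain", "replicate", "cell_id", "divisions", "end_state")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0) stop("no cell records in ", path, call. = FALSE)

  line_no <- seq_len(nrow(df)) + 1L  # header is line 1
  div <- suppressWarnings(as.numeric(df$divisions))
  bad <- is.na(div) | div < 0 | div != floor(div)
  if (any(bad)) {
    stop("line ", line_no[which(bad)[1]],
         ": 'divisions' must be a nonnegative integer, got '",
         df$divisions[which(bad)[1]], "'", call. = FALSE)
  }
  bad <- !df$end_state %in% c("dead", "alive")
  if (any(bad)) {
    stop("line ", line_no[which(bad)[1]],
         ": 'end_state' must be 'dead' or 'alive', got '",
         df$end_state[which(bad)[1]], "'", call. = FALSE)
  }

  out <- data.frame(strain = df$strain, replicate = df$replicate,
                    cell_id = df$cell_id, divisions = as.integer(div),
                    end_state = ifelse(df$end_state == "alive",
                                       "censored", "dead"),
                    stringsAsFactors = FALSE)
  if ("division_times" %in% names(df)) {
    out$division_times <- lapply(seq_len(nrow(df)), function(i) {
      s <- df$division_times[i]
      if (is.na(s) || s == "") return(numeric(0))
      t <- suppressWarnings(as.numeric(strsplit(s, ";", fixed = TRUE)[[1]]))
      if (anyNA(t)) {
        stop("line ", line_no[i], ": malformed 'division_times'",
             call. = FALSE)
      }
      if (is.unsorted(t, strictly = TRUE)) {
        stop("line ", line_no[i],
             ": 'division_times' must be strictly increasing", call. = FALSE)
      }
      t
    })
    n_times <- lengths(out$division_times)
    has_times <- n_times > 0
    mism <- has_times & n_times != out$divisions
    if (any(mism)) {
      stop("line ", line_no[which(mism)[1]],
           ": 'divisions' disagrees with the number of division times",
           call. = FALSE)
    }
  }
  class(out) <- c("cell_table", "data.frame")
  out
}

#' Write / read a per-strain screen table
#'
#' Tab-separated per-strain results: fit parameters, predicted
#' full-distribution statistics, and (after [classify_screen()])
#' fold-change, Z and significance versus wild-type.
#'
#' @param screen Data frame from [fit_strains()] or [classify_screen()].
#' @param path File path.
#' @return `path` (write) or the data frame (read), invisibly for write.
#' @export
write_screen_table <- function(screen, path) {
  stopifnot(is.data.frame(screen))
  df <- screen
  num <- vapply(df, is.numeric, TRUE) & !vapply(df, is.integer, TRUE)
  df[num] <- lapply(df[num], function(x) sprintf("%.6g", x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_screen_table
#' @export
read_screen_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one term per line, tab-separated as term id, description,
#' then member genes. Returns the named term -> genes list consumed by
#' [hypergeom_enrichment()].
#'
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  fgsea::gmtPathways(path)
}

#' Read a plain-text gene list
#'
#' One identifier per line; blank lines ignored.
#'
#' @param path File path.
#' @return Character vector of identifiers.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x)]
}

#' Read a dose-response table
#'
#' TSV with columns `level` (relative protein amount) and `mean_rls`
#' (generations), one row per strain/condition.
#'
#' @param path File path.
#' @return Data frame with numeric `level` and `mean_rls`.
#' @export
read_dose_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("level", "mean_rls")
  if (!all(need %in% names(df))) {
    stop("dose table needs columns 'level' and 'mean_rls'", call. = FALSE)
  }
  df$level <- suppressWarnings(as.numeric(df$level))
  df$mean_rls <- suppressWarnings(as.numeric(df$mean_rls))
  if (anyNA(df$level) || anyNA(df$mean_rls)) {
    stop("non-numeric entries in dose table", call. = FALSE)
  }
  df
}

#' Read a simulation configuration
#'
#' YAML or JSON (by extension) describing a simulated screen: a `design`
#' block with [aging_sim_params()] fields (`seed` mandatory) and a
#' `strains` list of `{strain, r, alpha}` entries, plus optional
#' `wildtype`. See `inst/extdata/screen_config.yaml` for a worked
#' example.
#'
#' @param path Config file path.
#' @return List with `design` (an `aging_sim_params`), `strain_specs`
#'   (data frame) and `wildtype_id`.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (is.null(cfg$design) || is.null(cfg$strains)) {
    stop("config must contain 'design' and 'strains' blocks", call. = FALSE)
  }
  if (is.null(cfg$design$seed)) {
    stop("config design must set a 'seed' (reproducibility is enforced)",
         call. = FALSE)
  }
  strains <- if (is.data.frame(cfg$strains)) cfg$strains else {
    do.call(rbind, lapply(cfg$strains, function(s)
      data.frame(strain = s$strain, r = as.numeric(s$r),
                 alpha = as.numeric(s$alpha), stringsAsFactors = FALSE)))
  }
  design_args <- cfg$design
  design_args$true_params <- weibull_params(strains$r[1], strains$alpha[1])
  design <- do.call(aging_sim_params, design_args)
  list(design = design, strain_specs = strains,
       wildtype_id = cfg$wildtype %||% strains$strain[1])
}
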