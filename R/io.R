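# Tabular interchange (strict TSV), cohort serialization, run configuration.

#' Read a tab-separated table with schema validation
#'
#' UTF-8, tab-delimited, '.' decimal, header row required. Missing required
#' columns raise a named error; NA/NaN in a required column raises an error
#' with the offending line number (header = line 1). Extra columns are
#' preserved.
#'
#' @param path file path.
#' @param required_cols column names that must be present and complete.
#' @return data frame.
#' @export
read_tabular <- function(path, required_cols = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE, fileEncoding = "UTF-8")
  miss <- setdiff(required_cols, names(df))
  if (length(miss)) {
    stop("missing required column(s) in ", basename(path), ": ",
         paste(miss, collapse = ", "))
  }
  for (col in required_cols) {
    bad <- which(is.na(df[[col]]))
    if (length(bad)) {
      stop("NA in required column '", col, "' of ", basename(path),
           " at line ", bad[1] + 1L)
    }
  }
  df
}

#' Write a tab-separated table
#'
#' @param df data frame.
#' @param path destination; parent directories are created.
#' @return `path`, invisibly.
#' @export
write_tabular <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a cohort to bead-level TSV files
#'
#' One bead table per sample (`beads_<sample>.tsv`: probe_id, bead_intensity,
#' is_negative_control), plus `samples.tsv` (the metadata) and `truth.tsv`
#' (ground-truth labels) when present.
#'
#' @param cohort output of [generate_cohort()].
#' @param dir destination directory.
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ba in cohort$arrays) {
    ids <- probe_ids(ba)
    if (is.matrix(ba$beads)) {
      long <- data.frame(
        probe_id = rep(ids, each = nrow(ba$beads)),
        bead_intensity = as.vector(ba$beads), stringsAsFactors = FALSE)
    } else {
      long <- data.frame(
        probe_id = rep(ids, lengths(ba$beads)),
        bead_intensity = unlist(ba$beads, use.names = FALSE),
        stringsAsFactors = FALSE)
    }
    long$is_negative_control <-
      as.integer(long$probe_id %in% ba$negative_control_ids)
    write_tabular(long, file.path(dir,
                                  paste0("beads_", ba$sample_id, ".tsv")))
  }
  write_tabular(cohort$meta, file.path(dir, "samples.tsv"))
  if (!is.null(cohort$truth)) {
    tr <- cohort$truth
    truth_df <- data.frame(
      gene_id = names(tr$true_log2_fc),
      true_log2_fc = unname(tr$true_log2_fc),
      is_de = as.integer(names(tr$true_log2_fc) %in% tr$de_gene_ids),
      is_expressed = as.integer(names(tr$true_log2_fc) %in%
                                  tr$expressed_gene_ids),
      is_treatment_responsive =
        as.integer(names(tr$true_log2_fc) %in% tr$treatment_responsive_ids),
      stringsAsFactors = FALSE)
    write_tabular(truth_df, file.path(dir, "truth.tsv"))
    writeLines(tr$heterogeneous_patient_ids,
               file.path(dir, "heterogeneous_patients.txt"))
  }
  invisible(dir)
}

#' Read one bead-level TSV into a bead array
#'
#' @param path a `beads_<sample>.tsv` written by [write_cohort()] (columns
#'   probe_id, bead_intensity, is_negative_control).
#' @param sample_id sample id; default derived from the file name.
#' @return a [bead_array()].
#' @export
read_bead_tsv <- function(path, sample_id = NULL) {
  df <- read_tabular(path, c("probe_id", "bead_intensity",
                             "is_negative_control"))
  if (is.null(sample_id)) {
    sample_id <- sub("^beads_", "", sub("\\.tsv$", "", basename(path)))
  }
  beads <- split(df$bead_intensity, df$probe_id)
  neg <- unique(df$probe_id[df$is_negative_control == 1])
  bead_array(sample_id, beads, neg)
}

#' Read a whole cohort directory written by [write_cohort()]
#'
#' @param dir the cohort directory.
#' @return list with `arrays` and `meta`.
#' @export
read_cohort <- function(dir) {
  meta <- read_tabular(file.path(dir, "samples.tsv"),
                       c("sample_id", "subject_id", "group", "timepoint",
                         "treated"))
  arrays <- lapply(meta$sample_id, function(s) {
    read_bead_tsv(file.path(dir, paste0("beads_", s, ".tsv")), s)
  })
  names(arrays) <- meta$sample_id
  list(arrays = arrays, meta = meta)
}

#' Import a series-matrix-style expression table
#'
#' Import shim for externally summarized expression matrices (probe rows,
#' sample columns, first column = probe id), so that public data can enter
#' the pipeline at the normalization stage. No presence information is
#' available in such tables, so every probe is treated as assessed.
#'
#' @param path TSV file.
#' @param meta sample metadata covering the table's sample columns.
#' @param scale `"raw"` or `"log2"` depending on the table's units.
#' @return an `expr_matrix`.
#' @export
import_expression_table <- function(path, meta, scale = c("raw", "log2")) {
  scale <- match.arg(scale)
  df <- read_tabular(path)
  ids <- df[[1]]
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- ids
  if (!all(colnames(values) %in% meta$sample_id)) {
    stop("metadata missing samples: ",
         paste(setdiff(colnames(values), meta$sample_id), collapse = ", "))
  }
  meta <- meta[match(colnames(values), meta$sample_id), , drop = FALSE]
  structure(list(values = values, scale = scale,
                 presence = NULL, group_active = NULL,
                 assessed = ids, sample_meta = meta,
                 groups = cohort_groups(meta), probe_calls = NULL),
            class = "expr_matrix")
}

#' Pipeline run configuration
#'
#' Bundles the simulation configuration and every stage parameter with its
#' default. The configuration round-trips through a key=value file via
#' [write_run_config()] / [read_run_config()].
#'
#' @param sim a [sim_config()].
#' @param mad_multiplier bead outlier rule multiplier.
#' @param mad_zero_policy `"strict"` or `"retain_all"`.
#' @param detection_alpha detection-call significance level.
#' @param window_size,confidence Cyber-t settings.
#' @param flag_k heterogeneity flag multiplier.
#' @param quality_threshold qPCR replicate QC threshold.
#' @return list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), mad_multiplier = 2,
                       mad_zero_policy = "strict", detection_alpha = 0.05,
                       window_size = 101, confidence = 10, flag_k = 2,
                       quality_threshold = 0.65) {
  structure(list(sim = sim, mad_multiplier = mad_multiplier,
                 mad_zero_policy = mad_zero_policy,
                 detection_alpha = detection_alpha,
                 window_size = window_size, confidence = confidence,
                 flag_k = flag_k, quality_threshold = quality_threshold),
            class = "run_config")
}

#' Write a run configuration as key=value lines
#'
#' @param config a [run_config()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  flat <- c(config$sim[setdiff(names(config$sim), "contamination_gene_ids")],
            list(contamination_gene_ids =
                   config$sim$contamination_gene_ids),
            config[setdiff(names(config), "sim")])
  lines <- vapply(names(flat), function(k) {
    v <- flat[[k]]
    paste0(k, "=", if (is.null(v)) "" else paste(v, collapse = ","))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a run configuration written by [write_run_config()]
#'
#' @param path the key=value file.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, function(x) if (length(x) > 1) x[2] else "", "")
  parse_val <- function(v, character_ok = FALSE) {
    if (v == "") return(NULL)
    parts <- strsplit(v, ",")[[1]]
    num <- suppressWarnings(as.numeric(parts))
    if (!anyNA(num) && !character_ok) num else parts
  }
  get <- function(k, character_ok = FALSE) {
    i <- match(k, keys)
    if (is.na(i)) return(NULL)
    parse_val(vals[i], character_ok)
  }
  sim_args <- setdiff(names(formals(sim_config)), "contamination_gene_ids")
  sim_vals <- lapply(sim_args, get)
  names(sim_vals) <- sim_args
  sim_vals <- sim_vals[!vapply(sim_vals, is.null, TRUE)]
  sim_vals$contamination_gene_ids <- get("contamination_gene_ids",
                                         character_ok = TRUE)
  sim <- do.call(sim_config, sim_vals)
  run_args <- setdiff(names(formals(run_config)), "sim")
  run_vals <- lapply(run_args, function(k) {
    get(k, character_ok = k == "mad_zero_policy")
  })
  names(run_vals) <- run_args
  run_vals <- run_vals[!vapply(run_vals, is.null, TRUE)]
  do.call(run_config, c(list(sim = sim), run_vals))
}
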