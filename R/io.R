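#' Readers and writers for the pipeline's tabular formats
#'
#' All readers accept tab- or comma-delimited text; the delimiter is
#' auto-detected from the header line and reported via a message. Empty cells
#' are read as missing (`NA`). Validation failures name the offending record
#' rather than silently coercing.
#'
#' @name methresp-io
NULL

# Sniff tab vs comma from the first line; ties go to tab.
detect_delim <- function(path) {
  line1 <- readLines(path, n = 1L, warn = FALSE)
  if (length(line1) == 0) stop("empty file: ", path, call. = FALSE)
  n_tab <- lengths(regmatches(line1, gregexpr("\t", line1, fixed = TRUE)))
  n_com <- lengths(regmatches(line1, gregexpr(",", line1, fixed = TRUE)))
  delim <- if (n_com > n_tab) "," else "\t"
  rlang::inform(sprintf("reading %s as %s-delimited", basename(path),
                        if (delim == ",") "comma" else "tab"),
                class = "methresp_io")
  delim
}

read_delim_quiet <- function(path) {
  readr::read_delim(path, delim = detect_delim(path), show_col_types = FALSE,
                    progress = FALSE, na = c("", "NA"))
}

#' Read a beta-value matrix
#'
#' Expects delimited text whose first column holds probe ids and whose header
#' row holds sample ids.
#'
#' @param path Path to a TSV/CSV file.
#' @param scale Declared measurement scale, `"array"` (values in (0,1)) or
#'   `"pyro"` (percent in \[0,100\]).
#' @return A [beta_matrix()]; row and column order follow the file.
#' @export
read_beta_matrix <- function(path, scale = c("array", "pyro")) {
  scale <- match.arg(scale)
  df <- read_delim_quiet(path)
  if (ncol(df) < 2) stop("beta matrix needs a probe id column plus samples", call. = FALSE)
  ids <- as.character(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric beta values in ", path, call. = FALSE)
  rownames(vals) <- ids
  beta_matrix(vals, scale)
}

#' Write a beta matrix as TSV
#'
#' @param bm A [beta_matrix()].
#' @param path Output path. The scale is not stored in the file; pass it again
#'   when reading back.
#' @export
write_beta_matrix <- function(bm, path) {
  readr::write_tsv(as_tibble.beta_matrix(bm), path)
  invisible(path)
}

sample_groups <- c("NT", "pCR", "pIR")
preservation_levels <- c("FF", "FFPE")
region_classes <- c("promoter", "body", "intergenic")
island_classes <- c("island", "shore", "shelf", "open_sea")
probe_flags <- c("xy", "cross_reactive", "snp")

check_enum <- function(x, allowed, what, id) {
  bad <- !is.na(x) & !(x %in% allowed)
  if (any(bad)) {
    k <- which(bad)[1]
    stop(sprintf("unknown %s '%s' for record '%s' (allowed: %s)",
                 what, x[k], id[k], paste(allowed, collapse = ", ")),
         call. = FALSE)
  }
  invisible(x)
}

#' Read a sample sheet
#'
#' Required columns: `sample_id`, `group` (NT/pCR/pIR). Optional:
#' `preservation` (FF/FFPE), `batch`, `cohort` (discovery/validation).
#'
#' @param path Path to a TSV/CSV file.
#' @return A tibble, one row per sample.
#' @export
read_sample_sheet <- function(path) {
  df <- read_delim_quiet(path)
  need <- c("sample_id", "group")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stop("sample sheet missing column(s): ",
                             paste(miss, collapse = ", "), call. = FALSE)
  df$sample_id <- as.character(df$sample_id)
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup) > 0) stop("duplicated sample id(s): ",
                            paste(dup, collapse = ", "), call. = FALSE)
  check_enum(df$group, sample_groups, "group", df$sample_id)
  if ("preservation" %in% names(df)) {
    check_enum(df$preservation, preservation_levels, "preservation", df$sample_id)
  }
  if ("cohort" %in% names(df)) {
    check_enum(df$cohort, c("discovery", "validation"), "cohort", df$sample_id)
  }
  tibble::as_tibble(df)
}

#' Read a probe annotation manifest
#'
#' Required columns: `probe_id`, `chrom`, `pos` (1-based, Illumina manifest
#' convention), `region_class` (promoter/body/intergenic), `island_class`
#' (island/shore/shelf/open_sea). Optional `flags`: comma-separated subset of
#' xy, cross_reactive, snp (empty = none).
#'
#' @param path Path to a TSV/CSV file.
#' @return A tibble, one row per probe; `flags` is a list-column of
#'   character vectors.
#' @export
read_manifest <- function(path) {
  df <- read_delim_quiet(path)
  need <- c("probe_id", "chrom", "pos", "region_class", "island_class")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stop("manifest missing column(s): ",
                             paste(miss, collapse = ", "), call. = FALSE)
  df$probe_id <- as.character(df$probe_id)
  dup <- unique(df$probe_id[duplicated(df$probe_id)])
  if (length(dup) > 0) stop("duplicated probe id(s): ",
                            paste(dup, collapse = ", "), call. = FALSE)
  if (any(is.na(df$pos)) || any(df$pos < 1)) {
    k <- which(is.na(df$pos) | df$pos < 1)[1]
    stop("invalid 1-based position for probe '", df$probe_id[k], "'", call. = FALSE)
  }
  check_enum(df$region_class, region_classes, "region_class", df$probe_id)
  check_enum(df$island_class, island_classes, "island_class", df$probe_id)
  if (!"flags" %in% names(df)) df$flags <- ""
  df$flags <- purrr::map(df$flags, function(f) {
    if (is.na(f) || !nzchar(f)) return(character(0))
    out <- strsplit(f, ",", fixed = TRUE)[[1]]
    out <- trimws(out)
    out[nzchar(out)]
  })
  purrr::iwalk(df$flags, function(f, i) {
    check_enum(f, probe_flags, "flag", rep(df$probe_id[i], length(f)))
  })
  tibble::as_tibble(df)
}

#' Read a BED4 interval file
#'
#' BED convention: 0-based half-open intervals. Lines are
#' `chrom<TAB>start<TAB>end<TAB>name`; track/browser lines and `#` comments are
#' skipped.
#'
#' @param path Path to a BED file.
#' @return A tibble with columns `chrom`, `start`, `end`, `name`.
#' @export
read_intervals <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  if (length(lines) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), name = character()))
  }
  parts <- strsplit(lines, "[\t ]+")
  nf <- lengths(parts)
  if (any(nf < 3)) stop("BED line with fewer than 3 fields: ",
                        lines[which(nf < 3)[1]], call. = FALSE)
  df <- tibble::tibble(
    chrom = purrr::map_chr(parts, 1),
    start = as.numeric(purrr::map_chr(parts, 2)),
    end   = as.numeric(purrr::map_chr(parts, 3)),
    name  = purrr::map_chr(parts, function(p) if (length(p) >= 4) p[4] else NA_character_)
  )
  if (any(is.na(df$start)) || any(is.na(df$end))) {
    stop("non-numeric BED coordinates in ", path, call. = FALSE)
  }
  bad <- df$start >= df$end
  if (any(bad)) {
    k <- which(bad)[1]
    stop(sprintf("BED interval with start >= end: %s:%d-%d (%s)",
                 df$chrom[k], df$start[k], df$end[k],
                 ifelse(is.na(df$name[k]), "unnamed", df$name[k])), call. = FALSE)
  }
  df
}

#' Write a result table as TSV
#'
#' Round-trips losslessly through [read_table_tsv()] for the pipeline's result
#' tibbles (list-columns such as manifest `flags` are flattened to
#' comma-separated strings).
#'
#' @param x A data frame.
#' @param path Output path.
#' @export
write_table <- function(x, path) {
  x <- dplyr::mutate(x, dplyr::across(
    dplyr::where(is.list),
    function(col) purrr::map_chr(col, paste, collapse = ",")
  ))
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname write_table
#' @return `read_table_tsv()` returns a tibble.
#' @export
read_table_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  na = c("", "NA"))
}

#' Run configuration and metadata
#'
#' A run configuration is a YAML key-value file holding the seed, analysis
#' thresholds and file paths. `write_run_metadata()` records the seed, a hash
#' of the configuration and package/R versions next to a run's outputs so a
#' run can be reproduced.
#'
#' @param path Path to a YAML config file.
#' @return `read_run_config()`: a named list with defaults filled in
#'   (`seed = 1`, `q_max = 0.05`, `db_min = 0.15`, `sd_min = 0.2`).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(seed = 1L, q_max = 0.05, db_min = 0.15, sd_min = 0.2)
  utils::modifyList(defaults, as.list(cfg))
}

#' @rdname read_run_config
#' @param config Named list as returned by `read_run_config()`.
#' @param out_dir Directory in which to write `run_metadata.yaml`.
#' @export
write_run_metadata <- function(config, out_dir) {
  meta <- list(
    seed = config$seed,
    config_hash = rlang::hash(config),
    package_version = as.character(utils::packageVersion("methresp")),
    r_version = as.character(getRversion()),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  path <- file.path(out_dir, "run_metadata.yaml")
  yaml::write_yaml(meta, path)
  invisible(path)
}
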