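#' Read a BED file of 0-based half-open intervals
#'
#' Accepts 3+ tab-separated columns; `track`/`browser`/comment lines are
#' skipped with a log record; a name column, when present, becomes the
#' interval names. Non-integer coordinates or `end <= start` raise a
#' parse error with the offending line number.
#'
#' @param path File path.
#' @return A named `GRanges` (1-based internally; see [write_bed()] for
#'   the round trip).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  skip <- grepl("^(track|browser|#)", lines) | !nzchar(lines)
  if (any(skip)) cw_log("skipping ", sum(skip), " non-data line(s) in ", path)
  keep <- which(!skip)
  if (!length(keep)) cw_stop("no intervals in ", path,
                             class = "cellwise_parse_error")
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  rows <- lapply(seq_along(keep), function(i) {
    f <- fields[[i]]
    ln <- keep[i]
    if (length(f) < 3) {
      cw_stop("line ", ln, ": fewer than 3 columns",
              class = "cellwise_parse_error")
    }
    s <- suppressWarnings(as.numeric(f[2]))
    e <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s) || is.na(e) || s != round(s) || e != round(e)) {
      cw_stop("line ", ln, ": non-integer coordinate",
              class = "cellwise_parse_error")
    }
    if (e <= s) {
      cw_stop("line ", ln, ": end <= start", class = "cellwise_parse_error")
    }
    data.frame(chrom = f[1], start = as.integer(s), end = as.integer(e),
               name = if (length(f) >= 4) f[4] else NA_character_,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1L, df$end))
  if (!all(is.na(df$name))) names(gr) <- df$name
  gr
}

#' Write intervals as BED (0-based half-open)
#'
#' @param intervals A `GRanges` (names become the BED name column) or a
#'   `data.frame` with `chrom`, `start`, `end` and optionally
#'   `peak_id`/`name`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_bed <- function(intervals, path) {
  if (inherits(intervals, "GRanges")) {
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(intervals)),
                     start = GenomicRanges::start(intervals) - 1L,
                     end = GenomicRanges::end(intervals),
                     name = if (is.null(names(intervals))) NA_character_
                            else names(intervals),
                     stringsAsFactors = FALSE)
  } else {
    df <- intervals
    nm <- if (!is.null(df$name)) df$name else df$peak_id
    df <- data.frame(chrom = df$chrom, start = df$start, end = df$end,
                     name = if (is.null(nm)) NA_character_ else nm,
                     stringsAsFactors = FALSE)
  }
  if (all(is.na(df$name))) df$name <- NULL
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a feature x sample matrix from TSV
#'
#' Expects a header row of sample ids and feature ids in the first
#' column. Duplicate feature ids are an error; non-numeric cells raise a
#' parse error with coordinates. `NA` tokens are allowed only with
#' `missing_ok = TRUE` (methylation tables).
#'
#' @param path File path.
#' @param missing_ok Allow missing values.
#' @return Numeric matrix with feature rownames and sample colnames.
#' @export
read_matrix <- function(path, missing_ok = FALSE) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    cw_stop("duplicate feature id(s): ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "),
            class = "cellwise_parse_error")
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(m, 2, as.numeric))) & !is.na(m),
                 arr.ind = TRUE)
    if (nrow(bad)) {
      cw_stop("non-numeric cell at feature '", ids[bad[1, 1]],
              "', sample '", colnames(m)[bad[1, 2]], "'",
              class = "cellwise_parse_error")
    }
    m <- apply(m, 2, as.numeric)
  }
  if (!missing_ok && anyNA(m)) {
    cw_stop("missing values present; use missing_ok = TRUE",
            class = "cellwise_parse_error")
  }
  rownames(m) <- ids
  m
}

#' Write a feature x sample matrix as TSV
#'
#' @param m Matrix with dimnames.
#' @param path Output path.
#' @param id_col Header of the feature-id column.
#' @return Invisibly, the path.
#' @export
write_matrix <- function(m, path, id_col = "feature_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a methylation table with paired beta and coverage columns
#'
#' Serializes beta and coverage side by side (`<sample>.beta`,
#' `<sample>.cov` per sample), the interchange format for methylation
#' data.
#'
#' @param beta,coverage Sites x samples matrices.
#' @param path File path.
#' @return `write_methylation` returns the path invisibly;
#'   `read_methylation` returns `list(beta, coverage)`.
#' @export
write_methylation <- function(beta, coverage, path) {
  stopifnot(identical(dim(beta), dim(coverage)))
  out <- data.frame(site_id = rownames(beta), stringsAsFactors = FALSE)
  for (s in colnames(beta)) {
    out[[paste0(s, ".beta")]] <- beta[, s]
    out[[paste0(s, ".cov")]] <- coverage[, s]
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_methylation
#' @export
read_methylation <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- df[[1]]
  bcols <- grep("\\.beta$", names(df), value = TRUE)
  samples <- sub("\\.beta$", "", bcols)
  beta <- as.matrix(df[, paste0(samples, ".beta"), drop = FALSE])
  coverage <- as.matrix(df[, paste0(samples, ".cov"), drop = FALSE])
  dimnames(beta) <- dimnames(coverage) <- list(ids, samples)
  list(beta = beta, coverage = coverage)
}

#' Default pipeline configuration
#'
#' All simulator, marker, estimator and model settings of
#' [run_pipeline()] in one nested list, serializable to YAML with
#' [write_config()]. The defaults are the package's reference study
#' conditions.
#'
#' @param seed Integer seed propagated to every stochastic stage.
#' @return Nested configuration list (class `run_config`).
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    simulate = list(
      n_individuals = 50,
      alpha = c(neuron = 24, astrocyte = 12, microglia = 3,
                oligodendrocyte = 12, endothelial = 3),
      adjacency_sd = 0.3,
      neuropil_weight = 1.0,
      condition_shift = c(-1.2, 0, 0, 0, 0),
      n_genes = 500, n_peaks = 600, n_meth_sites = 150,
      expr_markers_per_type = 80,
      peak_markers = c(neuron = 80, astrocyte = 30, microglia = 30,
                       oligodendrocyte = 30, endothelial = 30),
      meth_markers_per_type = 20,
      marker_fold = 8,
      dispersion = 0.05,
      coverage_mean = 30,
      missing_rate = 0.05,
      da_fraction = 0.05,
      da_log2fc = 0.8
    ),
    markers = list(fc_fold = 4, min_mean = 1000, upstream = 5000),
    models = c("none", "shuffled", "ordered_factor", "continuous_true"),
    estimate = list(n_levels = 5)
  ), class = "run_config")
}

#' Read and write pipeline configuration files (YAML)
#'
#' Configurations round-trip: `read_config(write_config(cfg, f))` equals
#' `cfg`.
#'
#' @param config A configuration list (see [default_config()]).
#' @param path File path.
#' @return `write_config` the path, invisibly; `read_config` the
#'   configuration list.
#' @export
write_config <- function(config, path) {
  # yaml serializes named atomic vectors as plain sequences; promote them
  # to maps so names survive the round trip
  promote <- function(x) {
    if (is.list(x)) return(lapply(x, promote))
    if (is.atomic(x) && !is.null(names(x))) return(as.list(x))
    x
  }
  yaml::write_yaml(promote(unclass(config)), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (f in c("alpha", "condition_shift", "peak_markers")) {
    if (!is.null(cfg$simulate[[f]])) {
      cfg$simulate[[f]] <- unlist(cfg$simulate[[f]])
    }
  }
  cfg$models <- unlist(cfg$models)
  structure(cfg, class = "run_config")
}
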