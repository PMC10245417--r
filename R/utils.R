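# internal helpers shared across modules

cw_stop <- function(..., class = "cellwise_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

cw_log <- function(...) {
  message("[cellwise] ", ...)
}

# rescale a numeric vector so min -> 0 and max -> 1; constant input -> all 0
rescale01 <- function(x) {
  r <- range(x, na.rm = TRUE)
  if (r[2] - r[1] <= 0) {
    return(rep(0, length(x)))
  }
  (x - r[1]) / (r[2] - r[1])
}

# centered log-ratio and its inverse (softmax); p must be strictly positive
clr <- function(p) log(p) - mean(log(p))

clr_inv <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

# draw one Dirichlet(alpha) vector
rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g <- alpha # degenerate underflow guard
  g / sum(g)
}

is_count_matrix <- function(m) {
  is.matrix(m) && is.numeric(m) && all(m >= 0) && all(abs(m - round(m)) < 1e-8)
}

# features x samples matrix sanity check with informative errors
check_matrix <- function(m, what = "matrix") {
  if (!is.matrix(m) || !is.numeric(m)) {
    cw_stop(what, " must be a numeric matrix (features x samples)")
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    cw_stop(what, " must have feature rownames and sample colnames")
  }
  invisible(m)
}

# 0-based half-open intervals (data.frame chrom/start/end) -> GRanges (1-based)
intervals_to_granges <- function(df) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  bad <- which(df$end <= df$start)
  if (length(bad)) {
    cw_stop("malformed intervals (end <= start) at rows: ",
            paste(head(bad, 5), collapse = ", "), class = "cellwise_parse_error")
  }
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
  if (!is.null(df$peak_id)) names(gr) <- df$peak_id
  if (!is.null(df$name)) names(gr) <- df$name
  gr
}
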