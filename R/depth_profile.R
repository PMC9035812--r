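# Mapped-base-count statistics from per-base depth tables. "Mapped base
# count" is the number of genomic positions whose coverage depth meets the
# stability threshold (DP 10 by convention); normalising it per 0.5 Gb of raw
# read data makes libraries of different size comparable.

#' Read a per-base depth table
#'
#' Consumes the 3-column TSV dialect produced by per-base depth export of
#' alignment toolkits (`chrom`, 1-based `pos`, `depth`), including the sparse
#' variant: positions absent from the table are depth 0. Chromosome lengths
#' must be declared so sparse tables can be densified.
#'
#' @param path TSV file (no header).
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param sample sample name (default: file name).
#' @param raw_read_gb gigabases of raw reads behind the sample (optional).
#' @return A [per_base_depth()].
#' @export
read_depth_table <- function(path, chrom_lengths,
                             sample = basename(path),
                             raw_read_gb = NA_real_) {
  stopifnot(is.numeric(chrom_lengths), !is.null(names(chrom_lengths)))
  dv <- lapply(chrom_lengths, function(L) integer(L))
  if (file.exists(path) && file.size(path) > 0) {
    dt <- data.table::fread(path, header = FALSE, sep = "\t",
                            colClasses = "character")
    if (ncol(dt) < 3L) stop("depth table needs 3 columns: chrom, pos, depth")
    chrom <- dt[[1]]
    pos <- suppressWarnings(as.integer(dt[[2]]))
    depth <- suppressWarnings(as.numeric(dt[[3]]))
    bad <- which(is.na(pos) | is.na(depth) | depth < 0 |
                   depth != floor(depth))
    if (length(bad)) {
      stop(sprintf("depth table parse error at line %d: '%s'", bad[1],
                   paste(unlist(dt[bad[1]]), collapse = "\t")))
    }
    unknown <- which(!chrom %in% names(chrom_lengths))
    if (length(unknown)) {
      stop(sprintf("unknown chromosome '%s' at line %d", chrom[unknown[1]],
                   unknown[1]))
    }
    oob <- which(pos < 1L | pos > chrom_lengths[chrom])
    if (length(oob)) {
      stop(sprintf("position out of range at line %d", oob[1]))
    }
    for (ch in unique(chrom)) {
      sel <- chrom == ch
      dv[[ch]][pos[sel]] <- as.integer(depth[sel])
    }
  }
  per_base_depth(dv, sample = sample, raw_read_gb = raw_read_gb)
}

#' Write a per-base depth table
#'
#' @param x a [per_base_depth()].
#' @param path output TSV path.
#' @param sparse write only non-zero positions (default), or every position.
#' @return `path`, invisibly.
#' @export
write_depth_table <- function(x, path, sparse = TRUE) {
  stopifnot(inherits(x, "per_base_depth"))
  rows <- lapply(names(x$depths), function(ch) {
    d <- x$depths[[ch]]
    i <- if (sparse) which(d > 0L) else seq_along(d)
    if (length(i) == 0L) return(NULL)
    data.table::data.table(chrom = ch, pos = i, depth = d[i])
  })
  dt <- data.table::rbindlist(rows)
  if (nrow(dt) == 0L) {
    file.create(path)
  } else {
    data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, eol = "\n")
  }
  invisible(path)
}

#' Mapped base count at a depth threshold
#'
#' Number of positions whose depth meets the threshold. The conventional
#' reading of "bases above DP 10" is `depth >= min_dp`; `strict = TRUE`
#' switches to `depth > min_dp`.
#'
#' @param x a [per_base_depth()] or a numeric depth vector.
#' @param min_dp depth threshold (>= 1).
#' @param strict use `>` instead of `>=`.
#' @return Integer count. Non-increasing in `min_dp`.
#' @export
#' @examples
#' mapped_base_count(c(12, 9, 10, 11, 3), min_dp = 10)  # 3
mapped_base_count <- function(x, min_dp = 10L, strict = FALSE) {
  stopifnot(min_dp >= 1)
  v <- if (inherits(x, "per_base_depth")) unlist(x$depths, use.names = FALSE)
       else as.numeric(x)
  if (strict) sum(v > min_dp) else sum(v >= min_dp)
}

#' Normalise a count per 0.5 Gb of raw read data
#'
#' @param value the statistic to normalise (e.g. a mapped base count).
#' @param raw_read_gb gigabases of raw read data (> 0).
#' @return `value / raw_read_gb * 0.5`.
#' @export
#' @examples
#' normalize_per_half_gb(200, 2.0)  # 50
normalize_per_half_gb <- function(value, raw_read_gb) {
  if (!all(is.finite(raw_read_gb)) || any(raw_read_gb <= 0)) {
    stop("raw_read_gb must be positive")
  }
  value / raw_read_gb * 0.5
}

#' Per-variant coverage-depth distribution summary
#'
#' For each variant the mean DP across samples is taken; the distribution of
#' these per-variant means is then summarised by quantiles, per sample group
#' (the numeric skeleton of a per-group DP violin plot).
#'
#' @param m a [genotype_matrix()] with DP filled.
#' @param groups optional named character vector mapping sample name to group;
#'   default puts all samples in group `"all"`.
#' @param probs quantile probabilities.
#' @return data.frame with one row per group: `group`, `n_variants`, and one
#'   column per quantile (`min`, `q05`, `q25`, `median`, `q75`, `q95`, `max`
#'   for the default `probs`). Zero variants give a zero-row data.frame.
#' @export
variant_dp_summary <- function(m, groups = NULL,
                               probs = c(0, 0.05, 0.25, 0.5, 0.75, 0.95, 1)) {
  stopifnot(inherits(m, "genotype_matrix"))
  qnames <- c("min", "q05", "q25", "median", "q75", "q95", "max")
  if (length(probs) != 7) qnames <- paste0("q", format(probs))
  if (is.null(groups)) groups <- setNames(rep("all", n_samples(m)), m$samples)
  stopifnot(all(m$samples %in% names(groups)))
  out <- list()
  for (g in unique(groups[m$samples])) {
    cols <- m$samples[groups[m$samples] == g]
    dpg <- m$dp[, cols, drop = FALSE]
    mdp <- rowMeans(dpg, na.rm = TRUE)
    mdp <- mdp[is.finite(mdp)]
    if (length(mdp) == 0L) next
    q <- quantile(mdp, probs = probs, names = FALSE)
    row <- data.frame(group = g, n_variants = length(mdp),
                      stringsAsFactors = FALSE)
    row[qnames] <- as.list(q)
    out[[g]] <- row
  }
  if (length(out) == 0L) {
    res <- data.frame(group = character(), n_variants = integer())
    res[qnames] <- replicate(length(qnames), numeric(0), simplify = FALSE)
    return(res)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
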