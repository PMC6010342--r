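# All file formats are text, 0-based half-open (BED/bedGraph convention).
# Writers emit '#' header lines recording the package version and any
# run parameters (seed etc.); readers skip '#' and 'track' lines.
# Writes go to a temporary file renamed into place on success.

meta_header <- function(meta = NULL) {
  line <- paste0("# chromspread v",
                 as.character(utils::packageVersion("chromspread")))
  if (length(meta))
    line <- paste0(line, "; ",
                   paste(names(meta), unlist(meta), sep = "=", collapse = "; "))
  line
}

write_atomic <- function(lines, path) {
  tmp <- paste0(path, ".tmp")
  writeLines(lines, tmp)
  if (!file.rename(tmp, path)) stop("could not write ", path)
  invisible(path)
}

read_body_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & !grepl("^track", lines) & nzchar(lines)
  list(lines = lines[keep], lineno = which(keep))
}

split_fields <- function(lines) strsplit(lines, "\t", fixed = TRUE)

#' Read a BED file of peaks or gene models
#'
#' Peaks (`type = "peaks"`) take their summit from column 7 when present,
#' interpreted as an absolute 0-based coordinate (BED6+1 as written by
#' [write_bed()]); without a seventh column the interval midpoint is used
#' and a warning is issued. Genes (`type = "genes"`) require a strand
#' (`+`/`-`) in column 6. All coordinates are 0-based half-open; malformed
#' lines are reported with their line number.
#'
#' @param path File path.
#' @param type `"peaks"` or `"genes"`.
#' @return A peak data.frame (`chrom`, `start`, `end`, `id`, `summit`) or a
#'   gene data.frame (`chrom`, `start`, `end`, `id`, `score`, `strand`).
#' @export
read_bed <- function(path, type = c("peaks", "genes")) {
  type <- match.arg(type)
  body <- read_body_lines(path)
  fields <- split_fields(body$lines)
  nf <- lengths(fields)
  need <- if (type == "genes") 6L else 3L
  if (any(nf < need))
    stop(sprintf("%s line %d: expected >= %d columns",
                 path, body$lineno[which(nf < need)[1]], need))
  get <- function(i) vapply(fields, function(f)
    if (length(f) >= i) f[i] else NA_character_, character(1))
  chrom <- get(1)
  start <- suppressWarnings(as.numeric(get(2)))
  end <- suppressWarnings(as.numeric(get(3)))
  bad <- which(!is.finite(start) | !is.finite(end) | start >= end | start < 0)
  if (length(bad))
    stop(sprintf("%s line %d: invalid interval (start >= end or non-numeric)",
                 path, body$lineno[bad[1]]))
  id <- get(4)
  if (anyNA(id)) id <- sprintf("feat%05d", seq_along(chrom))
  if (type == "genes") {
    strand <- get(6)
    bad <- which(!strand %in% c("+", "-"))
    if (length(bad))
      stop(sprintf("%s line %d: unknown strand '%s'",
                   path, body$lineno[bad[1]], strand[bad[1]]))
    score <- suppressWarnings(as.numeric(get(5)))
    score[!is.finite(score)] <- 0
    return(data.frame(chrom = chrom, start = start, end = end, id = id,
                      score = score, strand = strand, stringsAsFactors = FALSE))
  }
  summit_raw <- get(7)
  if (all(is.na(summit_raw))) {
    warning("no summit column in ", path, "; using interval midpoints")
    summit <- floor((start + end) / 2)
  } else {
    summit <- suppressWarnings(as.numeric(summit_raw))
    bad <- which(!is.finite(summit) | summit < start | summit >= end)
    if (length(bad))
      stop(sprintf("%s line %d: summit outside [start, end)",
                   path, body$lineno[bad[1]]))
  }
  data.frame(chrom = chrom, start = start, end = end, id = id,
             summit = summit, stringsAsFactors = FALSE)
}

#' Write peaks or gene models as BED
#'
#' Genes are written as BED6; peaks as BED6+1 with the absolute 0-based
#' summit coordinate in column 7. A `#` header line records the package
#' version and any `meta` key=value pairs (e.g. the seed). Writing then
#' reading with [read_bed()] is an identity on the data columns.
#'
#' @param x Peak or gene data.frame (a `summit` column marks peaks).
#' @param path Output path.
#' @param meta Optional named list recorded in the header.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path, meta = NULL) {
  hdr <- meta_header(meta)
  if ("summit" %in% names(x)) {
    lines <- sprintf("%s\t%d\t%d\t%s\t0\t.\t%d", x$chrom, as.integer(x$start),
                     as.integer(x$end), x$id, as.integer(x$summit))
  } else {
    lines <- sprintf("%s\t%d\t%d\t%s\t%g\t%s", x$chrom, as.integer(x$start),
                     as.integer(x$end), x$id, x$score, x$strand)
  }
  invisible(write_atomic(c(hdr, lines), path))
}

#' Read a bedGraph into a fixed-bin track
#'
#' Records (0-based half-open, non-overlapping) are rebinned to `bin_bp` by
#' coverage-weighted mean; bases covered by no record count as zeros, and
#' their total is reported via `message()`. Overlapping records are an
#' error.
#'
#' @param path bedGraph file.
#' @param genome A [genome_spec()] naming the chromosomes and lengths.
#' @param bin_bp Target bin size.
#' @return A `raw`-kind [binned_track()] (use `kind` to relabel downstream).
#' @export
read_bedgraph <- function(path, genome, bin_bp) {
  stopifnot_genome(genome)
  body <- read_body_lines(path)
  fields <- split_fields(body$lines)
  if (any(lengths(fields) < 4))
    stop(sprintf("%s line %d: expected 4 columns",
                 path, body$lineno[which(lengths(fields) < 4)[1]]))
  chrom <- vapply(fields, `[`, character(1), 1)
  start <- as.numeric(vapply(fields, `[`, character(1), 2))
  end <- as.numeric(vapply(fields, `[`, character(1), 3))
  value <- as.numeric(vapply(fields, `[`, character(1), 4))
  bad <- which(!is.finite(start) | !is.finite(end) | !is.finite(value) |
                 start >= end | start < 0)
  if (length(bad))
    stop(sprintf("%s line %d: malformed record", path, body$lineno[bad[1]]))
  check_chroms(chrom, genome, "bedGraph")
  if (any(end > genome$chrom_lengths[chrom]))
    stop("bedGraph record extends past chromosome end in ", path)
  values <- list()
  uncovered <- 0
  for (ch in genome$chrom_names) {
    L <- genome$chrom_lengths[[ch]]
    nb <- n_bins(L, bin_bp)
    acc <- numeric(nb)
    sel <- which(chrom == ch)
    if (length(sel)) {
      o <- sel[order(start[sel])]
      if (any(start[o][-1] < end[o][-length(o)]))
        stop("overlapping bedGraph records on ", ch, " in ", path)
      for (i in o) {
        b0 <- floor(start[i] / bin_bp); b1 <- floor((end[i] - 1) / bin_bp)
        bins <- seq.int(b0, b1)
        ovl <- pmin(end[i], (bins + 1) * bin_bp) - pmax(start[i], bins * bin_bp)
        acc[bins + 1] <- acc[bins + 1] + value[i] * ovl
      }
      uncovered <- uncovered + L - sum(end[sel] - start[sel])
    } else {
      uncovered <- uncovered + L
    }
    widths <- pmin((seq_len(nb)) * bin_bp, L) - (seq_len(nb) - 1) * bin_bp
    values[[ch]] <- acc / widths
  }
  if (uncovered > 0)
    message(format(uncovered, big.mark = ","),
            " uncovered base(s) treated as 0 in ", path)
  binned_track(values, bin_bp, genome, kind = "raw")
}

#' Write a binned track as bedGraph
#'
#' Runs of equal-valued bins are collapsed into single records; the final
#' record of each chromosome is clipped to the chromosome length. Reading
#' back with [read_bedgraph()] at the same bin size reproduces the binned
#' values (to ~1e-9; values are printed with 17 significant digits).
#'
#' @param track A [binned_track()].
#' @param path Output path.
#' @param meta Optional named list recorded in the header.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, meta = NULL) {
  if (!inherits(track, "binned_track")) stop("expected a binned_track")
  bs <- track$bin_bp
  out <- lapply(names(track$values), function(ch) {
    v <- track$values[[ch]]
    r <- rle(v)
    ends_bin <- cumsum(r$lengths)
    starts_bin <- ends_bin - r$lengths
    L <- track$genome$chrom_lengths[[ch]]
    sprintf("%s\t%d\t%d\t%.17g", ch, as.integer(starts_bin * bs),
            as.integer(pmin(ends_bin * bs, L)), r$values)
  })
  invisible(write_atomic(c(meta_header(meta), unlist(out)), path))
}

#' Read / write an expression table
#'
#' Tab-separated with a header row (`gene_id`, `logfc`, `de`, `germline`)
#' and `#` comment lines, as produced by [generate_expression()].
#'
#' @param path File path.
#' @return data.frame with `gene_id`, `logfc`, logical `de` and `germline`.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("gene_id", "logfc")
  if (!all(need %in% names(df)))
    stop("expression table must have columns: ", paste(need, collapse = ", "))
  if ("de" %in% names(df)) df$de <- as.logical(df$de)
  if ("germline" %in% names(df)) df$germline <- as.logical(df$germline)
  df
}

#' @rdname read_expression
#' @param x Expression data.frame.
#' @param meta Optional named list recorded in the header.
#' @export
write_expression <- function(x, path, meta = NULL) {
  body <- c(paste(names(x), collapse = "\t"),
            do.call(sprintf, c(list(fmt = paste(
              ifelse(vapply(x, is.numeric, logical(1)), "%.17g", "%s"),
              collapse = "\t")), x)))
  invisible(write_atomic(c(meta_header(meta), body), path))
}

#' Read a chrom.sizes file into a genome spec
#'
#' Two tab-separated columns: chromosome name, length in bp.
#'
#' @param path File path.
#' @return A [genome_spec()].
#' @export
read_chrom_sizes <- function(path) {
  body <- read_body_lines(path)
  fields <- split_fields(body$lines)
  genome_spec(vapply(fields, `[`, character(1), 1),
              as.numeric(vapply(fields, `[`, character(1), 2)))
}

#' @rdname read_chrom_sizes
#' @param genome A [genome_spec()] to write.
#' @export
write_chrom_sizes <- function(genome, path) {
  stopifnot_genome(genome)
  invisible(write_atomic(
    sprintf("%s\t%d", genome$chrom_names, as.integer(genome$chrom_lengths)),
    path))
}

#' Read / write a confidence-band table
#'
#' Serializes a [bootstrap_ci()] object as TSV (`offset`, `mean`, `lower`,
#' `upper`, `sd_rep`) with the band parameters in `#` header lines so the
#' object round-trips.
#'
#' @param ci A `profile_ci`.
#' @param path File path.
#' @param meta Optional named list merged into the header.
#' @return `write_profile_ci`: `path` invisibly; `read_profile_ci`: a
#'   `profile_ci`.
#' @export
write_profile_ci <- function(ci, path, meta = NULL) {
  params <- list(n_summits = ci$n_summits, fraction = ci$subsample_fraction,
                 reps = ci$n_replicates, alpha = ci$alpha,
                 bin_bp = ci$bin_bp, flank_bp = ci$flank_bp)
  hdr <- c(meta_header(meta),
           sprintf("# param %s=%.17g", names(params), unlist(params)))
  body <- c("offset\tmean\tlower\tupper\tsd_rep",
            sprintf("%d\t%.17g\t%.17g\t%.17g\t%.17g", as.integer(ci$offsets),
                    ci$mean, ci$lower, ci$upper, ci$sd_rep))
  invisible(write_atomic(c(hdr, body), path))
}

#' @rdname write_profile_ci
#' @export
read_profile_ci <- function(path) {
  lines <- readLines(path)
  pl <- grep("^# param ", lines, value = TRUE)
  kv <- do.call(rbind, strsplit(sub("^# param ", "", pl), "=", fixed = TRUE))
  params <- stats::setNames(as.numeric(kv[, 2]), kv[, 1])
  df <- utils::read.delim(textConnection(lines[!grepl("^#", lines)]),
                          stringsAsFactors = FALSE)
  structure(list(offsets = df$offset, mean = df$mean, lower = df$lower,
                 upper = df$upper, sd_rep = df$sd_rep,
                 n_summits = as.integer(params[["n_summits"]]),
                 subsample_fraction = params[["fraction"]],
                 n_replicates = as.integer(params[["reps"]]),
                 alpha = params[["alpha"]],
                 bin_bp = params[["bin_bp"]], flank_bp = params[["flank_bp"]]),
            class = "profile_ci")
}
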