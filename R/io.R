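#' @importFrom stats median sd var mad optim rnorm runif rbeta rbinom quantile
#'   setNames complete.cases ks.test wilcox.test t.test fisher.test dhyper
#'   phyper predict
#' @importFrom utils read.table write.table read.csv write.csv head tail
NULL

# All genomic coordinates inside the package are 0-based half-open [start, end).
# Coordinates quoted from 1-based inclusive tables must be converted on input
# with `table_to_bed()`.

#' Convert 1-based inclusive coordinates to 0-based half-open
#'
#' Published coordinate tables are conventionally 1-based and inclusive of the
#' end base; internal coordinates are 0-based half-open. The conversion is
#' `start - 1, end`.
#'
#' @param start,end integer vectors of 1-based inclusive coordinates.
#' @return A data.frame with columns `start` and `end`, 0-based half-open.
#' @export
table_to_bed <- function(start, end) {
  stopifnot(all(start >= 1), all(end >= start))
  data.frame(start = start - 1L, end = end)
}

#' Construct a set of genomic regions
#'
#' Regions are labeled half-open intervals. `set_label`, when supplied, must be
#' one of `background`, `muscle`, `non_muscle`; `responder` is an optional
#' logical flag carried through the property analyses.
#'
#' @param chrom character chromosome names.
#' @param start,end 0-based half-open coordinates, `start < end`.
#' @param region_id unique identifiers; default `chrom:start-end`.
#' @param set_label optional set membership.
#' @param responder optional logical.
#' @param ... further per-region columns, recycled as in `data.frame()`.
#' @return data.frame of class `crm_regions`.
#' @export
genomic_regions <- function(chrom, start, end, region_id = NULL,
                            set_label = NULL, responder = NULL, ...) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(start >= end)) stop("regions must satisfy start < end")
  if (is.null(region_id)) region_id <- paste0(chrom, ":", start, "-", end)
  if (anyDuplicated(region_id)) stop("region_id values must be unique")
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   region_id = as.character(region_id),
                   stringsAsFactors = FALSE, ...)
  if (!is.null(set_label)) {
    set_label <- as.character(set_label)
    bad <- setdiff(unique(set_label), c("background", "muscle", "non_muscle"))
    if (length(bad)) stop("unknown set_label: ", paste(bad, collapse = ", "))
    df$set_label <- set_label
  }
  if (!is.null(responder)) df$responder <- as.logical(responder)
  class(df) <- c("crm_regions", "data.frame")
  df
}

#' Read a FASTA file
#'
#' @param path file path.
#' @return named character vector of uppercased sequences over `{A,C,G,T,N}`.
#' @export
read_fasta <- function(path) {
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) stop("malformed FASTA file '", path,
                                           "': ", conditionMessage(e)))
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) stop("FASTA sequence contains non-ACGTN characters: ",
                     paste(names(seqs)[bad], collapse = ", "))
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a BED file into genomic regions
#'
#' Requires at least three whitespace-separated columns. Coordinates are taken
#' as 0-based half-open (the BED convention). A fourth column, when present,
#' becomes `region_id`; columns five and six are kept as `score` and `strand`.
#' Records with `start >= end` are rejected with a warning.
#'
#' @param path file path.
#' @return `crm_regions` data.frame.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  if (!length(lines)) stop("empty BED file: ", path)
  fields <- strsplit(trimws(lines), "[ \t]+")
  ncol <- vapply(fields, length, 1L)
  if (any(ncol < 3L)) stop("BED records need >= 3 columns: ", path)
  chrom <- vapply(fields, `[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
  if (anyNA(start) || anyNA(end)) stop("non-numeric BED coordinates: ", path)
  keep <- start < end
  if (!all(keep)) {
    warning(sum(!keep), " BED record(s) with start >= end rejected")
    fields <- fields[keep]; chrom <- chrom[keep]
    start <- start[keep]; end <- end[keep]; ncol <- ncol[keep]
  }
  if (!length(chrom)) stop("no valid BED records in ", path)
  id <- ifelse(ncol >= 4L, vapply(fields, function(f) f[4L], ""),
               paste0(chrom, ":", start, "-", end))
  extra <- list()
  if (any(ncol >= 5L))
    extra$score <- suppressWarnings(as.numeric(
      ifelse(ncol >= 5L, vapply(fields, function(f) f[5L], ""), NA)))
  if (any(ncol >= 6L))
    extra$strand <- ifelse(ncol >= 6L, vapply(fields, function(f) f[6L], ""), "*")
  do.call(genomic_regions,
          c(list(chrom = chrom, start = start, end = end, region_id = id), extra))
}

#' Write regions as BED
#'
#' @param regions `crm_regions` data.frame.
#' @param path output path.
#' @param score optional numeric vector for column 5.
#' @param strand optional strand vector for column 6.
#' @export
write_bed <- function(regions, path, score = NULL, strand = NULL) {
  df <- data.frame(regions$chrom, regions$start, regions$end, regions$region_id)
  if (is.null(score) && !is.null(regions$score)) score <- regions$score
  if (is.null(strand) && !is.null(regions$strand)) strand <- regions$strand
  if (!is.null(score)) df[[5L]] <- score
  if (!is.null(strand)) { if (ncol(df) < 5L) df[[5L]] <- 0; df[[6L]] <- strand }
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct a position frequency matrix
#'
#' @param motif_id identifier.
#' @param counts 4 x L nonnegative matrix, rows A, C, G, T, `L >= 4`, every
#'   column sum positive.
#' @param name display name, default `motif_id`.
#' @return object of class `pfm`.
#' @export
pfm <- function(motif_id, counts, name = motif_id) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) stop("PFM must have 4 rows (A, C, G, T)")
  if (ncol(counts) < 4L) stop("PFM must have length >= 4")
  if (any(counts < 0)) stop("PFM counts must be nonnegative")
  if (any(colSums(counts) <= 0)) stop("every PFM column sum must be > 0")
  rownames(counts) <- c("A", "C", "G", "T")
  structure(list(motif_id = motif_id, name = name, counts = counts),
            class = "pfm")
}

#' @export
print.pfm <- function(x, ...) {
  cat("PFM", x$motif_id, "(", x$name, "), length", ncol(x$counts), "\n")
  print(round(x$counts, 2))
  invisible(x)
}

#' Read JASPAR flat-format position frequency matrices
#'
#' Accepts the JASPAR 2008 flat dialect: a `>id name` header followed by four
#' count rows, either bare (in A, C, G, T order) or prefixed with the base
#' letter and optional brackets, e.g. `A [ 4 19 0 ]`.
#'
#' @param path file path.
#' @return list of [pfm] objects.
#' @export
read_jaspar_pfm <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (!length(heads)) stop("no JASPAR header lines ('>') in ", path)
  out <- vector("list", length(heads))
  bounds <- c(heads, length(lines) + 1L)
  for (i in seq_along(heads)) {
    block <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    if (length(block) != 4L)
      stop("JASPAR block must have exactly 4 count rows: ",
           lines[heads[i]])
    hdr <- strsplit(sub("^>", "", trimws(lines[heads[i]])), "[ \t]+")[[1L]]
    id <- hdr[1L]
    nm <- if (length(hdr) > 1L) paste(hdr[-1L], collapse = " ") else hdr[1L]
    labelled <- grepl("^[ACGTacgt][ \t\\[]", trimws(block))
    rows <- lapply(block, function(ln) {
      ln <- trimws(ln)
      lab <- NA_character_
      if (grepl("^[ACGTacgt]([ \t\\[]|$)", ln)) {
        lab <- toupper(substr(ln, 1L, 1L))
        ln <- sub("^[ACGTacgt]", "", ln)
      }
      ln <- gsub("[][]", " ", ln)
      vals <- suppressWarnings(as.numeric(strsplit(trimws(ln), "[ \t]+")[[1L]]))
      if (anyNA(vals)) stop("unparseable JASPAR count row: ", ln)
      list(lab = lab, vals = vals)
    })
    labs <- vapply(rows, function(r) r$lab, "")
    if (all(labelled)) {
      if (!setequal(labs, c("A", "C", "G", "T")))
        stop("JASPAR block rows must cover A, C, G, T exactly: ", id)
      ord <- match(c("A", "C", "G", "T"), labs)
    } else if (any(labelled)) {
      stop("mixed labelled and unlabelled JASPAR rows in block ", id)
    } else ord <- 1:4
    m <- try(do.call(rbind, lapply(rows[ord], function(r) r$vals)),
             silent = TRUE)
    if (inherits(m, "try-error") || !is.matrix(m))
      stop("ragged JASPAR count rows in block ", id)
    out[[i]] <- pfm(id, m, nm)
  }
  names(out) <- vapply(out, function(p) p$motif_id, "")
  out
}

#' Write PFMs in JASPAR flat format
#'
#' @param pfms list of [pfm] objects.
#' @param path output path.
#' @export
write_jaspar_pfm <- function(pfms, path) {
  if (inherits(pfms, "pfm")) pfms <- list(pfms)
  con <- file(path, "w"); on.exit(close(con))
  for (p in pfms) {
    writeLines(paste0(">", p$motif_id, " ", p$name), con)
    for (b in c("A", "C", "G", "T"))
      writeLines(paste0(b, " [ ", paste(p$counts[b, ], collapse = " "), " ]"),
                 con)
  }
  invisible(path)
}

#' Construct a per-base score track
#'
#' @param chrom chromosome name.
#' @param start 0-based start of the covered span.
#' @param values numeric per-base scores.
#' @param kind `"bounded01"` (phastCons-like, values in `[0,1]`) or
#'   `"unbounded"` (phyloP-like).
#' @return object of class `score_track`.
#' @export
score_track <- function(chrom, start, values, kind = c("bounded01", "unbounded")) {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  if (anyNA(values)) stop("score track values must not be NA")
  if (kind == "bounded01" && (any(values < 0) || any(values > 1)))
    stop("bounded01 track values must lie in [0, 1]")
  structure(list(chrom = chrom, start = as.integer(start), values = values,
                 kind = kind), class = "score_track")
}

#' @export
print.score_track <- function(x, ...) {
  cat("score_track", x$chrom, sprintf("[%d, %d)", x$start,
                                      x$start + length(x$values)),
      x$kind, "\n")
  invisible(x)
}

#' Read a bedGraph file as a per-base score track
#'
#' Intervals are 0-based half-open and must not overlap; gaps between covered
#' intervals are filled with 0. Only single-chromosome tracks are supported.
#'
#' @param path file path.
#' @param kind track kind, `"auto"` infers `bounded01` when all values lie in
#'   `[0, 1]`.
#' @return [score_track].
#' @export
read_score_track <- function(path, kind = c("auto", "bounded01", "unbounded")) {
  kind <- match.arg(kind)
  df <- read.table(path, header = FALSE, comment.char = "#",
                   col.names = c("chrom", "start", "end", "value"))
  df <- df[!grepl("^track", df$chrom), , drop = FALSE]
  if (!nrow(df)) stop("empty bedGraph file: ", path)
  if (length(unique(df$chrom)) != 1L)
    stop("multi-chromosome bedGraph tracks are not supported: ", path)
  df <- df[order(df$start), , drop = FALSE]
  if (any(df$start >= df$end)) stop("degenerate bedGraph interval in ", path)
  if (any(df$start[-1L] < df$end[-nrow(df)]))
    stop("overlapping bedGraph intervals in ", path)
  origin <- df$start[1L]
  values <- numeric(df$end[nrow(df)] - origin)
  for (i in seq_len(nrow(df)))
    values[(df$start[i] - origin + 1L):(df$end[i] - origin)] <- df$value[i]
  if (kind == "auto")
    kind <- if (all(values >= 0 & values <= 1)) "bounded01" else "unbounded"
  score_track(df$chrom[1L], origin, values, kind)
}

#' Write a score track as bedGraph
#'
#' Consecutive equal values are run-length collapsed.
#'
#' @param track [score_track].
#' @param path output path.
#' @export
write_score_track <- function(track, path) {
  r <- rle(track$values)
  ends <- track$start + cumsum(r$lengths)
  starts <- ends - r$lengths
  write.table(data.frame(track$chrom, starts, ends, r$values), path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Extract per-base track scores over a region
#'
#' Positions outside the track's covered span score 0.
#'
#' @param track [score_track].
#' @param start,end 0-based half-open region coordinates.
#' @return numeric vector of length `end - start`.
#' @export
track_values <- function(track, start, end) {
  stopifnot(start < end)
  pos <- seq.int(start, end - 1L)
  idx <- pos - track$start + 1L
  ok <- idx >= 1L & idx <= length(track$values)
  out <- numeric(length(pos))
  out[ok] <- track$values[idx[ok]]
  out
}

plate_columns <- c("clone_id", "insert_id", "set_label", "phase", "cell_type",
                   "tech_rep", "firefly_lru", "renilla_lru")

#' Read plate-reader luciferase measurements
#'
#' The CSV schema has one row per well: `clone_id, insert_id, set_label,
#' phase, cell_type, tech_rep, firefly_lru, renilla_lru`.
#'
#' @param path CSV path.
#' @return data.frame of well measurements.
#' @export
read_plate_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(plate_columns, names(df))
  if (length(miss))
    stop("plate CSV missing column(s): ", paste(miss, collapse = ", "))
  validate_wells(df[, plate_columns])
}

#' Write plate measurements as CSV
#'
#' @param wells data.frame of well measurements.
#' @param path output path.
#' @export
write_plate_csv <- function(wells, path) {
  write.csv(wells[, plate_columns], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_wells <- function(df) {
  if (any(!is.finite(df$firefly_lru)) || any(!is.finite(df$renilla_lru)))
    stop("luminescence values must be finite")
  if (any(df$firefly_lru < 0) || any(df$renilla_lru < 0))
    stop("luminescence values must be nonnegative")
  bad <- setdiff(unique(df$cell_type), c("fibroblast", "myoblast", "myotube"))
  if (length(bad)) stop("unknown cell_type: ", paste(bad, collapse = ", "))
  if (!all(df$phase %in% c(1L, 2L))) stop("phase must be 1 or 2")
  df
}

# IRanges helpers: internal intervals are 0-based half-open, IRanges is
# 1-based closed; the shift is confined to these two functions.
to_iranges <- function(start, end) IRanges::IRanges(start + 1L, end)
from_iranges <- function(ir) {
  data.frame(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}
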