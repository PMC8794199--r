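# Tab-delimited readers and writers for the pipeline's external formats.
# All coordinates are 0-based, half-open; BED files are native.

#' Read a genetic map
#'
#' Tab-delimited with a header line and columns `chrom`, `pos_bp`, `pos_cM`.
#'
#' @param path file path.
#' @return a [genetic_map()].
#' @export
read_genetic_map <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = c("character", "numeric", "numeric"))
  names(df) <- c("chrom", "pos_bp", "pos_cM")
  genetic_map(df)
}

#' @rdname read_genetic_map
#' @param map a [genetic_map()].
#' @export
write_genetic_map <- function(map, path) {
  df <- do.call(rbind, lapply(names(map$chroms), function(cn)
    cbind(chrom = cn, map$chroms[[cn]])))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a marker set (tab-delimited chrom, pos)
#' @param path file path.
#' @return a [marker_set()].
#' @export
read_marker_set <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t")
  marker_set(df[c("chrom", "pos")])
}

#' Read a BED annotation track
#'
#' Standard BED (0-based, half-open), 3+ columns; the class label is taken
#' from the 4th column when present, otherwise from `class`.
#'
#' @param path file path.
#' @param class class label when the file has no 4th column.
#' @return an [annotation_track()].
#' @export
read_bed_track <- function(path, class = "custom") {
  df <- read.table(path, header = FALSE, sep = "\t")
  names(df)[1:3] <- c("chrom", "start", "end")
  df$class <- if (ncol(df) >= 4) as.character(df[[4]]) else class
  annotation_track(df[c("chrom", "start", "end", "class")])
}

#' Write regions/intervals as BED
#' @param df data.frame whose first three columns are chrom, start, end;
#'   remaining columns are appended.
#' @param path file path.
#' @export
write_bed <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read/write an ancestry matrix
#'
#' Tab-delimited: rows are individuals (first column `individual`), columns
#' are markers labelled `chrom:pos`; values 0/1/2/NA.
#'
#' @param am an [ancestry_matrix()].
#' @param path file path.
#' @export
write_ancestry_matrix <- function(am, path) {
  d <- am$dosage
  colnames(d) <- paste0(am$markers$chrom, ":", am$markers$pos)
  df <- data.frame(individual = seq_len(nrow(d)), d, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_ancestry_matrix
#' @return `read_ancestry_matrix`: an [ancestry_matrix()].
#' @export
read_ancestry_matrix <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  d <- as.matrix(df[, -1, drop = FALSE])
  if (ncol(d) == 0)
    return(ancestry_matrix(matrix(integer(0), nrow(df), 0),
                           marker_set(data.frame(chrom = character(0),
                                                 pos = numeric(0)))))
  parts <- strsplit(colnames(d), ":", fixed = TRUE)
  chroms <- vapply(parts, `[`, "", 1)
  pos <- as.numeric(vapply(parts, `[`, "", 2))
  mk <- marker_set(data.frame(chrom = chroms, pos = pos))
  ord <- order(match(chroms, unique(mk$chrom)), pos)
  d <- d[, ord, drop = FALSE]
  dimnames(d) <- NULL
  ancestry_matrix(d, mk)
}

#' Write posterior triples (three columns per marker)
#' @param am an [ancestry_matrix()] with posteriors.
#' @param path file path.
#' @export
write_posteriors <- function(am, path) {
  stopifnot(!is.null(am$posteriors))
  p <- am$posteriors
  n <- dim(p)[1]; m <- dim(p)[2]
  flat <- matrix(aperm(p, c(1, 3, 2)), n, 3 * m)
  lab <- paste0(rep(paste0(am$markers$chrom, ":", am$markers$pos), each = 3),
                ":p", 0:2)
  colnames(flat) <- lab
  df <- data.frame(individual = seq_len(n), flat, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write haplotype tracts (BED-like, cM coordinates)
#' @param tracts tract data.frame from [simulate_admixed_population()].
#' @param path file path.
#' @export
write_tracts <- function(tracts, path) {
  write.table(tracts, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
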