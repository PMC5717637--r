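#' Read a nucleotide alignment from FASTA
#'
#' Reads an aligned FASTA file into a \code{DNAStringSet}, validating the
#' alignment invariants used throughout the package: all sequences equal
#' length, unique ids, alphabet restricted to A, C, G, T, N and the gap
#' character \code{-}.  Lower case is folded to upper and U is mapped to T.
#' IUPAC ambiguity codes other than N are rejected rather than silently
#' coerced.
#'
#' @param path path to a FASTA file.
#' @return A \code{DNAStringSet} of equal-width sequences.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1", "ACGT", ">s2", "ACGA"), fa)
#' aln <- readFasta(fa)
#' Biostrings::width(aln)
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  # read permissively (BStringSet) so case folding and U -> T mapping can
  # happen before the DNA alphabet is enforced
  aln <- Biostrings::readBStringSet(path)
  if (length(aln) == 0L) stop("empty input: no FASTA records in ", path)
  v <- as.character(aln)
  names(v) <- names(aln)
  validateAlignment(v)
}

#' Validate (and canonicalise) an alignment
#'
#' @param aln a \code{DNAStringSet} or named character vector.
#' @return The canonicalised \code{DNAStringSet} (upper case, U -> T).
#' @export
validateAlignment <- function(aln) {
  if (is.character(aln)) {
    if (is.null(names(aln))) names(aln) <- paste0("s", seq_along(aln))
    v <- toupper(gsub("U", "T", aln, ignore.case = TRUE))
    bad <- unique(unlist(strsplit(gsub("[ACGTN-]", "", v), "")))
    if (length(bad))
      stop("disallowed characters in alignment (only A,C,G,T,N,- ",
           "accepted): ", paste(bad, collapse = ", "))
    aln <- Biostrings::DNAStringSet(v)
  }
  if (length(aln) == 0L) stop("empty input: alignment has no sequences")
  w <- Biostrings::width(aln)
  if (length(unique(w)) != 1L)
    stop("alignment-length error: sequence lengths differ (",
         paste(unique(w), collapse = ", "), ")")
  if (w[1] < 1L) stop("alignment-length error: zero-length sequences")
  ids <- names(aln)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    stop("all records must carry an id")
  if (anyDuplicated(ids))
    stop("duplicate-id error: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  freq <- Biostrings::alphabetFrequency(aln, collapse = TRUE)
  allowed <- c("A", "C", "G", "T", "N", "-")
  extra <- setdiff(names(freq)[freq > 0], allowed)
  if (length(extra))
    stop("disallowed characters in alignment (only A,C,G,T,N,- accepted): ",
         paste(extra, collapse = ", "))
  aln
}

#' Trim an alignment to a site range
#'
#' Restricts every sequence to positions \code{from:to} (1-based,
#' inclusive), e.g. to drop an INDEL-bearing tRNA region so that a 702-bp
#' fragment becomes the 519-bp protein-coding alignment used for distance
#' and network analyses.
#'
#' @param aln \code{DNAStringSet} alignment.
#' @param from,to integer site bounds.
#' @return The trimmed \code{DNAStringSet}.
#' @export
trimAlignment <- function(aln, from, to) {
  aln <- validateAlignment(aln)
  w <- Biostrings::width(aln)[1]
  if (from < 1 || to > w || from > to)
    stop("site range [", from, ", ", to, "] outside alignment of width ", w)
  Biostrings::subseq(aln, start = from, end = to)
}

.canonGeno <- function(a, b) {
  ifelse(is.na(a) | is.na(b), NA_character_,
         paste(pmin(a, b), pmax(a, b), sep = "/"))
}

#' Construct a GenotypeTable
#'
#' @param calls character matrix (samples x loci) of "a/b" genotype strings
#'   (allele order irrelevant) with \code{NA} for missing; row and column
#'   names give sample ids and locus names.
#' @return A \code{GenotypeTable}.
#' @export
genotypeTable <- function(calls) {
  stopifnot(is.matrix(calls))
  samples <- rownames(calls)
  loci <- colnames(calls)
  if (is.null(samples) || is.null(loci))
    stop("calls matrix needs row (sample) and column (locus) names")
  canon <- calls
  for (j in seq_len(ncol(calls))) {
    cell <- calls[, j]
    parts <- strsplit(ifelse(is.na(cell), "NA/NA", cell), "/", fixed = TRUE)
    nall <- lengths(parts)
    if (any(nall != 2L))
      stop("malformed-genotype error at locus ", loci[j], ": cells ",
           paste(which(nall != 2L), collapse = ","),
           " do not hold exactly two alleles")
    a <- vapply(parts, `[`, "", 1L)
    b <- vapply(parts, `[`, "", 2L)
    a[a %in% c("NA", "", "?")] <- NA
    b[b %in% c("NA", "", "?")] <- NA
    bad <- xor(is.na(a), is.na(b))
    if (any(bad))
      stop("malformed-genotype error at locus ", loci[j],
           ": half-missing allele pair")
    canon[, j] <- .canonGeno(a, b)
  }
  new("GenotypeTable", samples = samples, loci = loci,
      calls = unname(canon))
}

#' Read a co-dominant genotype table
#'
#' Two layouts are accepted: \code{"pair"} — one column per locus holding
#' \code{"a/b"} strings — and \code{"twocol"} — two adjacent columns per
#' locus (headers like \code{L1.1}, \code{L1.2} or repeated \code{L1}).
#' \code{dialect = "auto"} picks \code{"twocol"} when no cell of the body
#' contains a \code{/}.  Allele pairs are unordered; the missing token
#' (default \code{"NA"}) may stand for a whole call or be absent.
#'
#' @param path delimited text file; first column = sample id, header row
#'   names the loci.
#' @param dialect one of "auto", "pair", "twocol".
#' @param sep field separator ("\\t" default; "," for CSV).
#' @param missing token denoting a missing call.
#' @return A \code{GenotypeTable}.
#' @export
readGenotypes <- function(path, dialect = c("auto", "pair", "twocol"),
                          sep = "\t", missing = "NA") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                   colClasses = "character", na.strings = missing,
                   strip.white = TRUE)
  if (nrow(df) == 0L) stop("empty-input error: no genotype rows")
  samples <- df[[1]]
  body <- df[, -1, drop = FALSE]
  if (dialect == "auto")
    dialect <- if (any(grepl("/", unlist(body), fixed = TRUE)))
      "pair" else "twocol"
  if (dialect == "pair") {
    calls <- as.matrix(body)
  } else {
    if (ncol(body) %% 2L != 0L)
      stop("malformed-genotype error: odd number of allele columns")
    loci <- sub("[._ ]?[12]$", "", colnames(body)[seq(1, ncol(body), 2)])
    calls <- matrix(NA_character_, nrow(body), length(loci),
                    dimnames = list(NULL, loci))
    for (j in seq_along(loci)) {
      a <- body[[2 * j - 1]]
      b <- body[[2 * j]]
      calls[, j] <- ifelse(is.na(a) & is.na(b), NA,
                           paste(a, b, sep = "/"))
    }
  }
  rownames(calls) <- samples
  genotypeTable(calls)
}

#' Read a per-sample trait table
#'
#' @param path delimited text; first column sample id, remaining columns
#'   real-valued traits (half-integer counts permitted).
#' @param sep field separator.
#' @return data.frame with rownames = sample ids, numeric trait columns.
#' @export
readTraits <- function(path, sep = "\t") {
  df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE)
  rownames(df) <- as.character(df[[1]])
  df <- df[, -1, drop = FALSE]
  if (!all(vapply(df, is.numeric, TRUE)))
    stop("trait columns must be numeric")
  if (!all(is.finite(as.matrix(df)))) stop("trait values must be finite")
  df
}

#' Read a geographic sample table
#'
#' @param path delimited text with columns \code{sample}, \code{x},
#'   \code{y}, \code{locality} and optionally \code{haplogroup}.
#' @param sep field separator.
#' @return data.frame with those columns (haplogroup NA if absent).
#' @export
readCoords <- function(path, sep = "\t") {
  df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE)
  need <- c("sample", "x", "y", "locality")
  if (!all(need %in% names(df)))
    stop("coordinate table needs columns: ", paste(need, collapse = ", "))
  if (!all(is.finite(df$x)) || !all(is.finite(df$y)))
    stop("coordinates must be finite")
  if (any(is.na(df$locality) | df$locality == ""))
    stop("localities must be non-empty")
  if (is.null(df$haplogroup)) df$haplogroup <- NA
  df[, c("sample", "x", "y", "locality", "haplogroup")]
}

.writeTSV <- function(x, path, config = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(config))
    writeLines(paste0("# seed=", config@seed, " grid=",
                      paste(config@gridSize, collapse = "x"),
                      " a=", config@weightA, " chain=",
                      paste(config@chain, collapse = "/")), con)
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write the pipeline report
#'
#' Writes per-stage tab-delimited tables plus a machine-readable verdict
#' summary (JSON) into \code{dir}.  Stages that did not run are noted in
#' the summary and produce no file.  The seed and configuration are echoed
#' in a comment line of every table.
#'
#' @param results a \code{StageResultBundle} list as returned by
#'   \code{\link{runPipeline}}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the manifest of files written.
#' @export
writeReport <- function(results, dir) {
  ran <- intersect(c("mtdna", "hwe", "ld", "fst", "clusters", "kappa",
                     "kaks", "landscape"),
                   names(results$tables))
  if (length(ran) == 0L) stop("empty results: no stage has run")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cfg <- results$config
  manifest <- character()
  for (nm in ran) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    .writeTSV(results$tables[[nm]], p, cfg)
    manifest <- c(manifest, p)
  }
  summ <- list(seed = cfg@seed,
               stages_run = ran,
               stages_skipped = setdiff(cfg@stages,
                                        names(results$tables)),
               verdict = if (!is.null(results$evidence))
                 results$evidence@verdict else "inconclusive",
               rationale = if (!is.null(results$evidence))
                 results$evidence@rationale else character(),
               flags = if (!is.null(results$evidence))
                 as.list(results$evidence@flags) else list(),
               kaks_ratio = if (!is.null(results$evidence))
                 results$evidence@kaksRatio else NA)
  p <- file.path(dir, "verdict.json")
  jsonlite::write_json(summ, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  manifest <- c(manifest, p)
  invisible(manifest)
}

#' Write an alignment to FASTA
#'
#' @param aln \code{DNAStringSet}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeFasta <- function(aln, path) {
  Biostrings::writeXStringSet(aln, path)
  invisible(path)
}

#' Write a GenotypeTable to delimited text (pair dialect)
#'
#' @param gt a \code{GenotypeTable}.
#' @param path output path.
#' @param sep field separator.
#' @return Invisibly, \code{path}.
#' @export
writeGenotypes <- function(gt, path, sep = "\t") {
  df <- data.frame(sample = gt@samples, genotypeCalls(gt),
                   check.names = FALSE)
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}
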