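# Canonical in-memory genotype container and PLINK text/binary I/O.
# Doses count copies of a declared per-marker reference allele; the
# declaration is carried with the object because signed-r phase analysis
# breaks silently if orientation differs between populations.

#' SNP genotype container
#'
#' The canonical representation used throughout the package: an
#' individuals x markers matrix of allele doses (0, 1, 2 copies of the
#' reference allele; `NA` = missing), a marker map, a sample table, and
#' the per-marker reference/alternate allele codes that pin the dose
#' orientation.
#'
#' @param doses Integer matrix, individuals x markers, entries in
#'   `c(0, 1, 2, NA)`.
#' @param map Data frame with columns `chrom` (autosome number, or any
#'   other code for non-autosomal/unmapped markers), `pos` (base pairs,
#'   1-based) and `name` (unique marker identifiers). Positions must be
#'   strictly increasing within a chromosome.
#' @param samples Data frame with columns `id` (unique) and `pop`.
#' @param ref_allele,alt_allele Character vectors, one allele code per
#'   marker; doses count `ref_allele`.
#' @return An object of class `genotypes`.
#' @export
genotypes <- function(doses, map, samples,
                      ref_allele = rep("A", ncol(doses)),
                      alt_allele = rep("B", ncol(doses))) {
  doses <- as.matrix(doses)
  storage.mode(doses) <- "integer"
  stopifnot(all(doses %in% c(0L, 1L, 2L, NA_integer_)),
            all(c("chrom", "pos", "name") %in% names(map)),
            all(c("id", "pop") %in% names(samples)),
            nrow(map) == ncol(doses),
            nrow(samples) == nrow(doses),
            !anyDuplicated(map$name),
            !anyDuplicated(samples$id),
            length(ref_allele) == ncol(doses),
            length(alt_allele) == ncol(doses))
  for (ch in unique(map$chrom)) {
    p <- map$pos[map$chrom == ch]
    if (any(diff(p) <= 0))
      stop("marker positions must be strictly increasing within chromosome ", ch)
  }
  rownames(doses) <- samples$id
  colnames(doses) <- map$name
  structure(list(doses = doses,
                 map = as.data.frame(map, stringsAsFactors = FALSE),
                 samples = as.data.frame(samples, stringsAsFactors = FALSE),
                 ref_allele = as.character(ref_allele),
                 alt_allele = as.character(alt_allele)),
            class = "genotypes")
}

#' @export
print.genotypes <- function(x, ...) {
  cat("genotypes: ", nrow(x$doses), " individuals x ", ncol(x$doses),
      " markers (", sum(is.na(x$doses)), " missing calls); populations: ",
      paste(unique(x$samples$pop), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Number of individuals / markers
#' @param g A [genotypes] object.
#' @return Integer count.
#' @export
n_individuals <- function(g) nrow(g$doses)

#' @rdname n_individuals
#' @export
n_markers <- function(g) ncol(g$doses)

#' Subset a genotypes object
#'
#' @param g A [genotypes] object.
#' @param individuals,markers Index vectors (integer, logical or names);
#'   `NULL` keeps everything.
#' @return A [genotypes] object.
#' @export
subset_genotypes <- function(g, individuals = NULL, markers = NULL) {
  stopifnot(inherits(g, "genotypes"))
  if (is.null(individuals)) individuals <- seq_len(nrow(g$doses))
  if (is.null(markers)) markers <- seq_len(ncol(g$doses))
  if (is.character(markers)) markers <- match(markers, g$map$name)
  if (is.character(individuals)) individuals <- match(individuals, g$samples$id)
  if (is.logical(markers)) markers <- which(markers)
  if (is.logical(individuals)) individuals <- which(individuals)
  genotypes(g$doses[individuals, markers, drop = FALSE],
            g$map[markers, , drop = FALSE],
            g$samples[individuals, , drop = FALSE],
            g$ref_allele[markers], g$alt_allele[markers])
}

# ---------------------------------------------------------------------------
# PLINK I/O

#' Read PLINK genotypes
#'
#' Reads either the text dialect (`prefix.ped` + `prefix.map`) or the
#' binary dialect (`prefix.bed` + `prefix.bim` + `prefix.fam`), whichever
#' is present (binary preferred when both exist).  Doses count the
#' reference allele: the A1 allele of the `.bim` file, or, for the `.ped`
#' dialect (which declares no allele order), the first allele of the first
#' heterozygous genotype at the marker (first non-missing allele if no
#' heterozygote exists).  The chosen allele is recorded in the returned
#' object so the orientation is reproducible and shareable across
#' populations.  The PLINK family ID is used as the population label.
#'
#' @param prefix Path prefix (without extension).
#' @return A [genotypes] object.
#' @export
read_plink <- function(prefix) {
  if (file.exists(paste0(prefix, ".bed"))) {
    read_plink_bed(prefix)
  } else if (file.exists(paste0(prefix, ".ped"))) {
    read_plink_ped(prefix)
  } else {
    stop("no PLINK files found at prefix '", prefix, "'")
  }
}

read_map_file <- function(path) {
  mp <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(mp) == 3L) mp <- cbind(mp[, 1:2], 0, mp[, 3])
  names(mp) <- c("chrom", "name", "cm", "pos")
  data.frame(chrom = mp$chrom, pos = as.integer(mp$pos), name = mp$name,
             stringsAsFactors = FALSE)
}

read_plink_ped <- function(prefix) {
  map <- read_map_file(paste0(prefix, ".map"))
  m <- nrow(map)
  lines <- readLines(paste0(prefix, ".ped"))
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  A1 <- matrix("0", n, m); A2 <- matrix("0", n, m)
  ids <- character(n); pops <- character(n)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) != 6L + 2L * m)
      stop("malformed .ped line ", i, ": expected ", 6L + 2L * m,
           " fields, found ", length(f))
    pops[i] <- f[1L]; ids[i] <- f[2L]
    A1[i, ] <- f[seq(7L, by = 2L, length.out = m)]
    A2[i, ] <- f[seq(8L, by = 2L, length.out = m)]
  }
  # Orientation rule: the reference allele is the first allele of the first
  # heterozygous genotype, falling back to the first non-missing allele for
  # markers with no heterozygote.  Together with write_plink() emitting
  # heterozygotes as "ref alt" this makes write -> read an exact inverse
  # for any marker carrying at least one heterozygote.
  ref <- rep("0", m); alt <- rep("0", m)
  doses <- matrix(NA_integer_, n, m)
  for (j in seq_len(m)) {
    a1 <- A1[, j]; a2 <- A2[, j]
    seen <- unique(c(rbind(a1, a2)))   # row-scan order
    seen <- seen[seen != "0"]
    if (length(seen) > 2L) {
      bad <- seen[3L]
      line <- which(a1 == bad | a2 == bad)[1L]
      stop("parse error at marker '", map$name[j], "' line ", line,
           ": allele '", bad, "' outside declared pair (",
           seen[1L], "/", seen[2L], ")")
    }
    if (length(seen) == 0L) next     # all calls missing
    het <- which(a1 != "0" & a2 != "0" & a1 != a2)
    ref[j] <- if (length(het)) a1[het[1L]] else seen[1L]
    alt[j] <- if (length(seen) == 2L) setdiff(seen, ref[j]) else "0"
    ok <- a1 != "0" & a2 != "0"
    doses[ok, j] <- (a1[ok] == ref[j]) + (a2[ok] == ref[j])
  }
  genotypes(doses, map, data.frame(id = ids, pop = pops,
                                   stringsAsFactors = FALSE), ref, alt)
}

read_plink_bed <- function(prefix) {
  map <- read.table(paste0(prefix, ".bim"), header = FALSE,
                    stringsAsFactors = FALSE)
  names(map) <- c("chrom", "name", "cm", "pos", "a1", "a2")
  fam <- read.table(paste0(prefix, ".fam"), header = FALSE,
                    stringsAsFactors = FALSE)
  n <- nrow(fam); m <- nrow(map)
  bytes_per_snp <- ceiling(n / 4)
  raw <- readBin(paste0(prefix, ".bed"), "raw",
                 n = 3 + m * bytes_per_snp)
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("parse error: '", prefix, ".bed' lacks the PLINK magic bytes")
  if (raw[3] != as.raw(0x01))
    stop("parse error: only SNP-major .bed files are supported")
  body <- raw[-(1:3)]
  if (length(body) != m * bytes_per_snp)
    stop("parse error: .bed payload size does not match .bim/.fam")
  # unpack 2-bit genotype codes, individuals packed low bits first
  ints <- as.integer(body)
  codes <- rbind(ints %% 4L, (ints %/% 4L) %% 4L,
                 (ints %/% 16L) %% 4L, ints %/% 64L)
  dim(codes) <- c(4L * bytes_per_snp, m)
  codes <- codes[seq_len(n), , drop = FALSE]
  # 00 -> 2 copies of A1, 10 (=2) -> het, 11 (=3) -> 0 copies, 01 (=1) -> NA
  doses <- matrix(NA_integer_, n, m)
  doses[codes == 0L] <- 2L
  doses[codes == 2L] <- 1L
  doses[codes == 3L] <- 0L
  genotypes(doses,
            data.frame(chrom = map$chrom, pos = as.integer(map$pos),
                       name = map$name, stringsAsFactors = FALSE),
            data.frame(id = as.character(fam[[2]]), pop = as.character(fam[[1]]),
                       stringsAsFactors = FALSE),
            as.character(map$a1), as.character(map$a2))
}

#' Write PLINK genotypes
#'
#' Writes a [genotypes] object as PLINK text (`.ped`/`.map`) or binary
#' (`.bed`/`.bim`/`.fam`, SNP-major with the standard magic bytes).  The
#' reference allele is written as A1 so that [read_plink()] reproduces the
#' same dose orientation.
#'
#' @param g A [genotypes] object with at least one marker.
#' @param prefix Output path prefix.
#' @param dialect `"bed"` (binary, default) or `"ped"` (text).
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(g, prefix, dialect = c("bed", "ped")) {
  stopifnot(inherits(g, "genotypes"))
  dialect <- match.arg(dialect)
  if (ncol(g$doses) == 0L) stop("refusing to write an empty marker set")
  n <- nrow(g$doses); m <- ncol(g$doses)
  if (dialect == "ped") {
    mp <- data.frame(g$map$chrom, g$map$name, 0, g$map$pos)
    write.table(mp, paste0(prefix, ".map"), quote = FALSE, sep = "\t",
                row.names = FALSE, col.names = FALSE)
    ref <- g$ref_allele; alt <- g$alt_allele
    con <- file(paste0(prefix, ".ped"), "w")
    on.exit(close(con))
    for (i in seq_len(n)) {
      d <- g$doses[i, ]
      a1 <- ifelse(is.na(d), "0", ifelse(d >= 1L, ref, alt))
      a2 <- ifelse(is.na(d), "0", ifelse(d == 2L, ref, alt))
      writeLines(paste(c(g$samples$pop[i], g$samples$id[i], 0, 0, 0, -9,
                         as.vector(rbind(a1, a2))), collapse = " "), con)
    }
  } else {
    bim <- data.frame(g$map$chrom, g$map$name, 0, g$map$pos,
                      g$ref_allele, g$alt_allele)
    write.table(bim, paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
                row.names = FALSE, col.names = FALSE)
    fam <- data.frame(g$samples$pop, g$samples$id, 0, 0, 0, -9)
    write.table(fam, paste0(prefix, ".fam"), quote = FALSE, sep = "\t",
                row.names = FALSE, col.names = FALSE)
    bytes_per_snp <- ceiling(n / 4)
    # dose (copies of A1) -> 2-bit code: 2 -> 00, 1 -> 10, 0 -> 11, NA -> 01
    code <- matrix(1L, 4L * bytes_per_snp, m)
    d <- g$doses
    cd <- matrix(NA_integer_, n, m)
    cd[d == 2L] <- 0L; cd[d == 1L] <- 2L; cd[d == 0L] <- 3L
    cd[is.na(d)] <- 1L
    code[seq_len(n), ] <- cd
    # rows beyond n are padding; PLINK pads with zero bits
    if (4L * bytes_per_snp > n) code[(n + 1L):(4L * bytes_per_snp), ] <- 0L
    packed <- code[seq(1, nrow(code), by = 4), , drop = FALSE] +
      4L * code[seq(2, nrow(code), by = 4), , drop = FALSE] +
      16L * code[seq(3, nrow(code), by = 4), , drop = FALSE] +
      64L * code[seq(4, nrow(code), by = 4), , drop = FALSE]
    con <- file(paste0(prefix, ".bed"), "wb")
    on.exit(close(con))
    writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
    writeBin(as.raw(packed), con)
  }
  invisible(prefix)
}

# ---------------------------------------------------------------------------

#' Per-chromosome marker map summary
#'
#' For each chromosome: spanned length (max - min position, Mb), marker
#' count, mean and SD of adjacent-marker gaps (Mb), and the longest gap.
#' An `Overall` row totals lengths and counts and pools all gaps.
#' Single-marker chromosomes are reported with length 0 and `NA` gaps,
#' with a warning.
#'
#' @param map Marker map data frame (`chrom`, `pos`, `name`).
#' @return Data frame with columns `chrom`, `length_mb`, `n_markers`,
#'   `mean_gap_mb`, `sd_gap_mb`, `max_gap_mb`.
#' @export
summarize_map <- function(map) {
  stopifnot(all(c("chrom", "pos") %in% names(map)))
  chroms <- unique(map$chrom)
  rows <- lapply(chroms, function(ch) {
    p <- sort(map$pos[map$chrom == ch])
    gaps <- diff(p) / 1e6
    if (length(gaps) == 0L) {
      warning("chromosome ", ch, " has a single marker; gaps undefined")
      data.frame(chrom = as.character(ch), length_mb = 0, n_markers = 1L,
                 mean_gap_mb = NA_real_, sd_gap_mb = NA_real_,
                 max_gap_mb = NA_real_, stringsAsFactors = FALSE)
    } else {
      data.frame(chrom = as.character(ch),
                 length_mb = (max(p) - min(p)) / 1e6,
                 n_markers = length(p),
                 mean_gap_mb = mean(gaps),
                 sd_gap_mb = if (length(gaps) > 1L) sd(gaps) else 0,
                 max_gap_mb = max(gaps), stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  all_gaps <- unlist(lapply(chroms, function(ch)
    diff(sort(map$pos[map$chrom == ch])) / 1e6))
  overall <- data.frame(chrom = "Overall",
                        length_mb = sum(out$length_mb),
                        n_markers = sum(out$n_markers),
                        mean_gap_mb = if (length(all_gaps)) mean(all_gaps) else NA_real_,
                        sd_gap_mb = if (length(all_gaps) > 1) sd(all_gaps) else NA_real_,
                        max_gap_mb = if (length(all_gaps)) max(all_gaps) else NA_real_,
                        stringsAsFactors = FALSE)
  rbind(out, overall)
}
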