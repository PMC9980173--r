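#' @importFrom data.table data.table fread fwrite setorder := .N .SD
#' @importFrom stats setNames
NULL

# ---- Assembly ----------------------------------------------------------------

#' Create a genome assembly description
#'
#' An assembly is the ordered set of chromosomes (names and lengths) over
#' which all binning, contact bookkeeping and X:A statistics are defined.
#' Chromosomes named \code{"chrX"} or \code{"X"} are flagged as sex
#' chromosomes unless \code{sex_chroms} is given explicitly; autosomes are
#' the complement.
#'
#' @param chrom_names character vector of unique chromosome names, in
#'   assembly order.
#' @param chrom_lengths integer vector of chromosome lengths in base pairs.
#' @param sex_chroms character vector of X-like chromosome names, or
#'   \code{NULL} to auto-detect \code{"chrX"}/\code{"X"}.
#' @return An object of class \code{"assembly"}: a list with
#'   \code{chrom_names}, \code{chrom_lengths} (named), \code{sex_chroms}
#'   and \code{autosomes}.
#' @export
assembly <- function(chrom_names, chrom_lengths, sex_chroms = NULL) {
  chrom_names <- as.character(chrom_names)
  if (length(chrom_names) == 0L) stop("no chromosomes")
  if (anyDuplicated(chrom_names)) stop("duplicate chromosome name")
  chrom_lengths <- as.numeric(chrom_lengths)
  if (length(chrom_lengths) != length(chrom_names))
    stop("chrom_names and chrom_lengths lengths differ")
  if (any(!is.finite(chrom_lengths)) || any(chrom_lengths <= 0))
    stop("non-positive length")
  if (is.null(sex_chroms)) {
    sex_chroms <- chrom_names[chrom_names %in% c("chrX", "X")]
  } else {
    sex_chroms <- as.character(sex_chroms)
    if (!all(sex_chroms %in% chrom_names))
      stop("sex_chroms not in chrom_names")
  }
  structure(list(
    chrom_names   = chrom_names,
    chrom_lengths = setNames(chrom_lengths, chrom_names),
    sex_chroms    = sex_chroms,
    autosomes     = setdiff(chrom_names, sex_chroms)
  ), class = "assembly")
}

#' Load an assembly from a chromosome-size table
#'
#' Reads a two-column TSV (\code{name<TAB>length}, no header) in the order
#' given, as produced by e.g. \code{samtools faidx} post-processing.
#'
#' @param path path to the chrom-size TSV.
#' @param sex_chroms optional explicit sex-chromosome names (overrides
#'   auto-detection of \code{chrX}/\code{X}).
#' @return An \code{\link{assembly}} object.
#' @export
load_assembly <- function(path, sex_chroms = NULL) {
  dt <- tryCatch(
    suppressWarnings(
      fread(path, header = FALSE, sep = "\t",
            colClasses = list(character = 1))),
    error = function(e) stop("cannot read chrom-size table: ", conditionMessage(e))
  )
  if (nrow(dt) == 0L) stop("no chromosomes")
  if (ncol(dt) < 2L) stop("chrom-size table needs two columns (name, length)")
  assembly(dt[[1]], as.numeric(dt[[2]]), sex_chroms = sex_chroms)
}

#' @export
print.assembly <- function(x, ...) {
  cat(sprintf("<assembly> %d chromosomes, %.1f Mb total; sex: %s\n",
              length(x$chrom_names), sum(x$chrom_lengths) / 1e6,
              if (length(x$sex_chroms)) paste(x$sex_chroms, collapse = ",")
              else "none"))
  invisible(x)
}

# ---- BinIndex ----------------------------------------------------------------

#' Tile an assembly into fixed-width bins
#'
#' Bins are 0-based half-open \code{[start, end)} intervals that tile each
#' chromosome without gaps or overlaps; the last bin of a chromosome may be
#' short. The row order defines the global bin ordinal (1-based in R).
#'
#' @param assembly an \code{\link{assembly}}.
#' @param bin_size bin width in base pairs (e.g. \code{1e6} for the scA/B
#'   grid, \code{250e3} for aggregate contact maps).
#' @return An object of class \code{"bin_index"}: list with \code{assembly},
#'   \code{bin_size} and \code{bins}, a \code{data.table} of
#'   (\code{chrom}, \code{start}, \code{end}).
#' @export
make_bins <- function(assembly, bin_size) {
  stopifnot(inherits(assembly, "assembly"))
  if (!is.numeric(bin_size) || length(bin_size) != 1L || bin_size <= 0)
    stop("bin_size must be a positive number")
  bins <- data.table::rbindlist(lapply(assembly$chrom_names, function(ch) {
    L <- assembly$chrom_lengths[[ch]]
    starts <- seq(0, L - 1, by = bin_size)
    data.table(chrom = ch, start = starts, end = pmin(starts + bin_size, L))
  }))
  # per-chromosome ordinal offset for O(1) position -> bin lookup
  nb <- as.integer(ceiling(assembly$chrom_lengths / bin_size))
  offset <- setNames(cumsum(c(0L, nb[-length(nb)])), assembly$chrom_names)
  structure(list(assembly = assembly, bin_size = bin_size, bins = bins,
                 n_bins_per_chrom = setNames(nb, assembly$chrom_names),
                 offset = offset),
            class = "bin_index")
}

#' @export
print.bin_index <- function(x, ...) {
  cat(sprintf("<bin_index> %d bins of %s bp over %d chromosomes\n",
              nrow(x$bins), format(x$bin_size, big.mark = ","),
              length(x$assembly$chrom_names)))
  invisible(x)
}

#' Number of bins in a bin index
#' @param bin_index a \code{\link{make_bins}} result.
#' @return integer bin count.
#' @export
n_bins <- function(bin_index) nrow(bin_index$bins)

#' Locate the bin containing a genomic position
#'
#' Positions are 1-based (pairs convention); the containing bin ordinal is
#' \code{floor((pos - 1) / bin_size)} within the chromosome, plus the
#' chromosome's offset. Vectorized over \code{chrom}/\code{pos}.
#'
#' @param bin_index a \code{\link{make_bins}} result.
#' @param chrom chromosome name(s).
#' @param pos 1-based position(s).
#' @return 1-based global bin ordinal(s) into \code{bin_index$bins}.
#' @export
locate_bin <- function(bin_index, chrom, pos) {
  len <- bin_index$assembly$chrom_lengths[chrom]
  if (anyNA(len)) stop("unknown chromosome: ",
                       paste(unique(chrom[is.na(len)]), collapse = ","))
  if (any(pos < 1 | pos > len)) stop("position out of range")
  as.integer(bin_index$offset[chrom] + floor((pos - 1) / bin_index$bin_size) + 1L)
}

# ---- BinTrack ----------------------------------------------------------------

#' Construct a per-bin scalar track
#'
#' @param bin_index a \code{\link{make_bins}} result.
#' @param values numeric vector, one finite value per bin.
#' @param kind label for the quantity, e.g. \code{"cpg_density"},
#'   \code{"compartment_sign"} or \code{"scab_mean"}.
#' @return An object of class \code{"bin_track"}.
#' @export
bin_track <- function(bin_index, values, kind = "generic") {
  stopifnot(inherits(bin_index, "bin_index"))
  values <- as.numeric(values)
  if (length(values) != n_bins(bin_index))
    stop("track length does not match bin count")
  if (any(!is.finite(values))) stop("track values must be finite")
  structure(list(bin_index = bin_index, values = values, kind = kind),
            class = "bin_track")
}

#' CpG-density reference track from a FASTA file
#'
#' Counts \code{CG} dinucleotides per bin (case-insensitive; dinucleotides
#' containing \code{N} never match) divided by bin width. A CG straddling a
#' bin boundary is credited to the bin of its first base. This is the
#' reference used to orient scA/B: compartment-A chromatin is CpG-rich.
#'
#' @param fasta_path FASTA whose sequence names and lengths match the
#'   assembly in \code{bin_index}.
#' @param bin_index the target grid.
#' @return A \code{\link{bin_track}} of kind \code{"cpg_density"}.
#' @export
cpg_density_track <- function(fasta_path, bin_index) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("cpg_density_track requires the Biostrings package")
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  asm <- bin_index$assembly
  if (!all(asm$chrom_names %in% names(seqs)))
    stop("FASTA/assembly mismatch: missing sequences")
  seqs <- seqs[asm$chrom_names]
  if (!all(Biostrings::width(seqs) == asm$chrom_lengths))
    stop("FASTA/assembly mismatch: sequence lengths differ")
  vals <- numeric(n_bins(bin_index))
  bins <- bin_index$bins
  for (ch in asm$chrom_names) {
    idx <- which(bins$chrom == ch)
    s <- seqs[[ch]]
    L <- length(s)
    for (i in idx) {
      # extend one base past the bin so a boundary-straddling CG counts here
      from <- bins$start[i] + 1L
      to <- min(bins$end[i] + 1L, L)
      n <- Biostrings::countPattern("CG", Biostrings::subseq(s, from, to))
      vals[i] <- n / (bins$end[i] - bins$start[i])
    }
  }
  bin_track(bin_index, vals, kind = "cpg_density")
}

#' Write / read a bin track as bedGraph
#'
#' Four-column bedGraph (\code{chrom start end value}), 0-based half-open.
#' @param track a \code{\link{bin_track}}.
#' @param path output path.
#' @return \code{write_bedgraph} returns \code{path} invisibly;
#'   \code{read_bedgraph} returns a \code{\link{bin_track}} on
#'   \code{bin_index}.
#' @export
write_bedgraph <- function(track, path) {
  dt <- data.table::copy(track$bin_index$bins)
  dt[, value := track$values]
  fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname write_bedgraph
#' @param bin_index grid the bedGraph must match exactly.
#' @export
read_bedgraph <- function(path, bin_index) {
  dt <- fread(path, header = FALSE, sep = "\t",
              col.names = c("chrom", "start", "end", "value"))
  key <- paste(bin_index$bins$chrom, bin_index$bins$start)
  m <- match(key, paste(dt$chrom, dt$start))
  if (anyNA(m)) stop("bedGraph does not cover the bin grid")
  bin_track(bin_index, dt$value[m])
}

# ---- Contacts ----------------------------------------------------------------

#' Construct a single cell's contact set
#'
#' Contacts are stored canonically: \code{chrom_a <= chrom_b} in assembly
#' order, and \code{pos_a <= pos_b} for intra-chromosomal contacts.
#' Positions are 1-based.
#'
#' @param cell_id cell identifier.
#' @param contacts \code{data.table}/\code{data.frame} with columns
#'   \code{chrom_a, pos_a, chrom_b, pos_b}.
#' @param assembly the \code{\link{assembly}} the coordinates refer to.
#' @param meta named list of metadata (donor, age, region, truth labels...).
#' @return An object of class \code{"cell_contacts"}; \code{$contacts} gains
#'   derived columns \code{is_intra} and \code{distance} (NA for inter).
#' @export
cell_contacts <- function(cell_id, contacts, assembly, meta = list()) {
  stopifnot(inherits(assembly, "assembly"))
  dt <- data.table::as.data.table(contacts)
  need <- c("chrom_a", "pos_a", "chrom_b", "pos_b")
  if (!all(need %in% names(dt))) stop("contacts need columns ",
                                      paste(need, collapse = ", "))
  dt <- dt[, need, with = FALSE]
  ok <- dt$chrom_a %in% assembly$chrom_names &
        dt$chrom_b %in% assembly$chrom_names
  if (!all(ok)) stop("unknown chromosome in contacts")
  ord <- setNames(seq_along(assembly$chrom_names), assembly$chrom_names)
  if (nrow(dt)) {
    flip <- ord[dt$chrom_a] > ord[dt$chrom_b] |
      (dt$chrom_a == dt$chrom_b & dt$pos_a > dt$pos_b)
    if (any(flip)) {
      tmp_c <- dt$chrom_a[flip]; tmp_p <- dt$pos_a[flip]
      dt[flip, `:=`(chrom_a = chrom_b, pos_a = pos_b)]
      dt[flip, `:=`(chrom_b = tmp_c, pos_b = tmp_p)]
    }
  }
  dt[, is_intra := chrom_a == chrom_b]
  dt[, distance := ifelse(is_intra, abs(pos_b - pos_a), NA_real_)]
  structure(list(cell_id = cell_id, contacts = dt,
                 assembly = assembly, meta = meta),
            class = "cell_contacts")
}

#' @export
print.cell_contacts <- function(x, ...) {
  cat(sprintf("<cell_contacts> %s: %d contacts (%.1f%% intra)\n",
              x$cell_id, nrow(x$contacts),
              if (nrow(x$contacts)) 100 * mean(x$contacts$is_intra) else NA))
  invisible(x)
}

#' Read / write contacts in 4DN pairs format
#'
#' The pairs dialect used: header lines start with \code{#}; body lines are
#' whitespace-separated \code{readID chr1 pos1 chr2 pos2 [strand1 strand2]}
#' with 1-based positions. Strand columns are ignored. gzip-compressed input
#' is read transparently. Duplicate records are kept as-is.
#'
#' @param path pairs file path (\code{.gz} allowed for reading).
#' @param assembly the \code{\link{assembly}} to validate against.
#' @param cell_id cell identifier (defaults to the file base name).
#' @param meta metadata list to attach.
#' @return \code{read_pairs}: a \code{\link{cell_contacts}};
#'   \code{write_pairs}: \code{path} invisibly.
#' @export
read_pairs <- function(path, assembly, cell_id = NULL, meta = list()) {
  if (is.null(cell_id))
    cell_id <- sub("\\.pairs(\\.gz)?$", "", basename(path))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  body <- which(!startsWith(lines, "#") & nzchar(trimws(lines)))
  if (length(body) == 0L)
    return(cell_contacts(cell_id,
                         data.table(chrom_a = character(), pos_a = numeric(),
                                    chrom_b = character(), pos_b = numeric()),
                         assembly, meta))
  fields <- strsplit(trimws(lines[body]), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 5L))
    stop("malformed pairs line ", body[which(nf < 5L)[1]],
         ": fewer than 5 fields")
  m <- t(vapply(fields, function(f) f[2:5], character(4)))
  pos_a <- suppressWarnings(as.numeric(m[, 2]))
  pos_b <- suppressWarnings(as.numeric(m[, 4]))
  bad <- which(is.na(pos_a) | is.na(pos_b))
  if (length(bad))
    stop("malformed pairs line ", body[bad[1]], ": non-numeric position")
  cell_contacts(cell_id,
                data.table(chrom_a = m[, 1], pos_a = pos_a,
                           chrom_b = m[, 3], pos_b = pos_b),
                assembly, meta)
}

#' @rdname read_pairs
#' @param cell a \code{\link{cell_contacts}} to serialize.
#' @export
write_pairs <- function(cell, path) {
  stopifnot(inherits(cell, "cell_contacts"))
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c("## pairs format v1.0",
               sprintf("#sample: %s", cell$cell_id),
               "#columns: readID chr1 pos1 chr2 pos2"), con)
  dt <- cell$contacts
  if (nrow(dt))
    writeLines(sprintf(".\t%s\t%d\t%s\t%d", dt$chrom_a, as.integer(dt$pos_a),
                       dt$chrom_b, as.integer(dt$pos_b)), con)
  invisible(path)
}
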