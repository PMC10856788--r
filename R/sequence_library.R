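DNA_BASES <- c("A", "C", "G", "T")

#' Construct a sensor sequence
#'
#' A sensor sequence is a single-stranded DNA oligo with fixed poly-C flanks
#' on both sides of a central variable region. The standard sensor design is
#' a 30-mer with (C)6 flanks and an 18-nt variable region; shorter toy
#' designs (smaller flanks / variable regions) are allowed for testing and
#' exhaustive checks.
#'
#' @param bases character scalar over the alphabet A/C/G/T.
#' @param name free-text label (e.g. `"original"`, `"N2-1"`).
#' @param flank_len number of fixed C bases on each flank (default 6).
#' @return an object of class `sensor_seq` with fields `bases`, `name`,
#'   `flank_len`, and `var_region` (the central variable-region string).
#' @export
sensor_seq <- function(bases, name = "", flank_len = 6L) {
  stopifnot(is.character(bases), length(bases) == 1L)
  flank_len <- as.integer(flank_len)
  n <- nchar(bases)
  chars <- strsplit(bases, "", fixed = TRUE)[[1]]
  if (any(!chars %in% DNA_BASES)) {
    stop(sensevo_error("invalid_alphabet",
      sprintf("sequence '%s' contains characters outside {A,C,G,T}", name)))
  }
  if (n < 2L * flank_len + 1L) {
    stop(sensevo_error("invalid_length",
      sprintf("sequence length %d leaves no variable region for flank length %d",
              n, flank_len)))
  }
  flank_idx <- c(seq_len(flank_len), seq.int(n - flank_len + 1L, n))
  if (any(chars[flank_idx] != "C")) {
    stop(sensevo_error("invalid_flank",
      sprintf("flanking %d-mers of '%s' must be all C", flank_len, bases)))
  }
  structure(
    list(bases = bases, name = name, flank_len = flank_len,
         var_region = substr(bases, flank_len + 1L, n - flank_len)),
    class = "sensor_seq"
  )
}

#' Validate a standard 30-mer sensor sequence
#'
#' Enforces the full sensor design contract: length exactly 30, alphabet
#' A/C/G/T, and hexa-C flanks (positions 1-6 and 25-30). Distinct error
#' conditions carry distinct classes: `sensevo_invalid_length`,
#' `sensevo_invalid_alphabet`, `sensevo_invalid_flank`.
#'
#' @inheritParams sensor_seq
#' @return a validated `sensor_seq` with an 18-nt variable region.
#' @examples
#' s <- validate_sequence("CCCCCCAGCCCTTCACCACCAACTCCCCCC", name = "original")
#' s$var_region
#' @export
validate_sequence <- function(bases, name = "") {
  stopifnot(is.character(bases), length(bases) == 1L)
  if (nchar(bases) != 30L) {
    stop(sensevo_error("invalid_length",
      sprintf("sensor sequence must be a 30-mer, got %d bases", nchar(bases))))
  }
  sensor_seq(bases, name = name, flank_len = 6L)
}

sensevo_error <- function(class, message) {
  structure(
    class = c(paste0("sensevo_", class), "sensevo_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  )
}

#' @export
print.sensor_seq <- function(x, ...) {
  cat(sprintf("<sensor_seq> %s\n  %s\n  variable region [%d nt]: %s\n",
              if (nzchar(x$name)) x$name else "(unnamed)",
              x$bases, nchar(x$var_region), x$var_region))
  invisible(x)
}

var_chars <- function(seq) strsplit(seq$var_region, "", fixed = TRUE)[[1]]

rebuild_bases <- function(parent, var_region) {
  flank <- strrep("C", parent$flank_len)
  paste0(flank, var_region, flank)
}

#' Enumerate the exactly-k-substitution mutant library
#'
#' Produces the complete, deduplicated library of sequences differing from
#' the parent at exactly `k` variable-region positions, each substituted
#' position set to one of the three bases different from the parent base;
#' flanks are never touched. For the standard 18-nt variable region and
#' `k = 3` this is choose(18,3) * 3^3 = 22,032 sequences. Members are
#' returned in lexicographic order of the full sequence string (C locale),
#' so enumeration is byte-reproducible.
#'
#' @param parent a `sensor_seq`.
#' @param k number of substituted positions, `0 <= k <=` variable-region length.
#' @param round_id integer round label carried in the library (default 1).
#' @return an object of class `mutant_library`: list with `parent`, `k`,
#'   `round_id`, and `members` (character vector of full sequence strings).
#' @export
enumerate_k_mutants <- function(parent, k, round_id = 1L) {
  stopifnot(inherits(parent, "sensor_seq"))
  L <- nchar(parent$var_region)
  k <- as.integer(k)
  if (k < 0L || k > L) {
    stop(sensevo_error("invalid_k",
      sprintf("k must be in [0, %d], got %d", L, k)))
  }
  pv <- var_chars(parent)
  if (k == 0L) {
    members <- parent$bases
  } else {
    pos_sets <- utils::combn(L, k, simplify = FALSE)
    # all k-tuples over the 3 alternative bases at each chosen position
    alt_idx <- expand.grid(rep(list(1:3), k), KEEP.OUT.ATTRS = FALSE)
    members <- character(length(pos_sets) * nrow(alt_idx))
    ptr <- 0L
    for (pos in pos_sets) {
      alts <- lapply(pos, function(p) setdiff(DNA_BASES, pv[p]))
      block <- matrix(rep(pv, nrow(alt_idx)), nrow = nrow(alt_idx), byrow = TRUE)
      for (j in seq_len(k)) {
        block[, pos[j]] <- alts[[j]][alt_idx[[j]]]
      }
      members[ptr + seq_len(nrow(alt_idx))] <-
        apply(block, 1L, paste0, collapse = "")
      ptr <- ptr + nrow(alt_idx)
    }
    flank <- strrep("C", parent$flank_len)
    members <- paste0(flank, members, flank)
    members <- sort(unique(members), method = "radix")
  }
  structure(
    list(parent = parent, k = k, round_id = as.integer(round_id),
         members = members),
    class = "mutant_library"
  )
}

#' @export
print.mutant_library <- function(x, ...) {
  cat(sprintf("<mutant_library> round %d: %d members at Hamming distance %d from '%s'\n",
              x$round_id, length(x$members), x$k,
              if (nzchar(x$parent$name)) x$parent$name else x$parent$bases))
  invisible(x)
}

#' Positions at which two sensor sequences differ
#'
#' Compares two flank-valid sensor sequences and reports the variable-region
#' positions (1-based within the variable region) where they differ, with the
#' from/to bases. Errors if the sequences differ anywhere in the flanks or
#' have different layouts.
#'
#' @param a,b `sensor_seq` objects with identical length and flank length.
#' @return a data.frame with columns `position`, `from`, `to`, sorted by
#'   position; zero rows when the sequences are identical.
#' @examples
#' orig <- validate_sequence("CCCCCCAGCCCTTCACCACCAACTCCCCCC", "original")
#' l114 <- validate_sequence("CCCCCCAGCACTACACAACCAACTCCCCCC", "L1-14")
#' diff_positions(orig, l114)  # positions 4, 7, 11, all to A
#' @export
diff_positions <- function(a, b) {
  stopifnot(inherits(a, "sensor_seq"), inherits(b, "sensor_seq"))
  if (nchar(a$bases) != nchar(b$bases) || a$flank_len != b$flank_len) {
    stop(sensevo_error("layout_mismatch",
      "sequences have different lengths or flank layouts"))
  }
  av <- var_chars(a); bv <- var_chars(b)
  idx <- which(av != bv)
  data.frame(position = idx, from = av[idx], to = bv[idx],
             stringsAsFactors = FALSE)
}

format_mutation_spec <- function(spec) {
  if (nrow(spec) == 0L) return("none")
  paste(sprintf("%d:%s>%s", spec$position, spec$from, spec$to), collapse = ",")
}

#' Write a mutant library to FASTA
#'
#' One single-line record per member; headers carry the member name, the
#' round id, and the mutation spec relative to the library parent in the
#' form `>{name}|round={r}|mut={pos:from>to,...}`.
#'
#' @param lib a `mutant_library`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_library_fasta <- function(lib, path) {
  stopifnot(inherits(lib, "mutant_library"))
  if (length(lib$members) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  headers <- vapply(seq_along(lib$members), function(i) {
    m <- sensor_seq(lib$members[i], flank_len = lib$parent$flank_len)
    spec <- diff_positions(lib$parent, m)
    sprintf("m%05d|round=%d|mut=%s", i, lib$round_id, format_mutation_spec(spec))
  }, character(1))
  xs <- Biostrings::DNAStringSet(lib$members)
  names(xs) <- headers
  Biostrings::writeXStringSet(xs, filepath = path, width = 20000L)
  invisible(path)
}

#' Read a mutant library from FASTA
#'
#' Inverse of [write_library_fasta()]: every record is validated against the
#' parent's layout (length, alphabet, poly-C flanks); a malformed record
#' fails with an error naming it.
#'
#' @param path FASTA file written by [write_library_fasta()].
#' @param parent the library parent (`sensor_seq`), needed to re-derive `k`.
#' @return a `mutant_library`.
#' @export
read_library_fasta <- function(path, parent) {
  stopifnot(inherits(parent, "sensor_seq"))
  xs <- Biostrings::readDNAStringSet(path)
  members <- as.character(xs)
  names(members) <- NULL
  round_id <- 1L
  if (length(members) > 0L) {
    hdr <- names(xs)[1]
    m <- regmatches(hdr, regexec("\\|round=([0-9]+)\\|", hdr))[[1]]
    if (length(m) == 2L) round_id <- as.integer(m[2])
  }
  k <- NA_integer_
  for (i in seq_along(members)) {
    s <- tryCatch(
      sensor_seq(members[i], flank_len = parent$flank_len),
      sensevo_error = function(e) {
        stop(sensevo_error("invalid_record",
          sprintf("FASTA record %d ('%s'): %s", i, names(xs)[i], conditionMessage(e))))
      })
    if (nchar(s$bases) != nchar(parent$bases)) {
      stop(sensevo_error("invalid_record",
        sprintf("FASTA record %d ('%s'): length %d does not match parent length %d",
                i, names(xs)[i], nchar(s$bases), nchar(parent$bases))))
    }
    d <- nrow(diff_positions(parent, s))
    if (is.na(k)) k <- d
  }
  structure(
    list(parent = parent, k = if (is.na(k)) 0L else k,
         round_id = round_id, members = sort(members, method = "radix")),
    class = "mutant_library"
  )
}

#' Library manifest as a data.frame
#'
#' @param lib a `mutant_library`.
#' @return data.frame with columns `sequence`, `name`, `round_id`,
#'   `hamming_to_parent`.
#' @export
library_manifest <- function(lib) {
  stopifnot(inherits(lib, "mutant_library"))
  hd <- vapply(lib$members, function(m) {
    nrow(diff_positions(lib$parent,
                        sensor_seq(m, flank_len = lib$parent$flank_len)))
  }, integer(1), USE.NAMES = FALSE)
  data.frame(
    sequence = lib$members,
    name = sprintf("m%05d", seq_along(lib$members)),
    round_id = lib$round_id,
    hamming_to_parent = hd,
    stringsAsFactors = FALSE
  )
}
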