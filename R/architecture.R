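#' Parse one read-architecture segment declaration
#'
#' A segment is declared as `"<K>:<body>"` where `K` is a one-letter kind code
#' and the body is a comma-separated list of nucleotide strings:
#'
#' * `B` — barcode: one or more mutually exclusive sequences of equal length
#'   over `A,C,G,T` (no `N`).
#' * `F` — fingerprint (UMI): a run of `N`s whose length is the fingerprint
#'   length.
#' * `S` — spacer: a single fixed sequence over `A,C,G,T`.
#' * `R` — the mappable read itself, declared as the single string `"N"`
#'   (variable length).
#' * `P` — partial adapter: a single sequence over `A,C,G,T` that may be
#'   truncated at a read end or absent entirely.
#'
#' Lower-case input is upper-cased.
#'
#' @param spec Character scalar, e.g. `"B:GTA,AAC"`.
#' @param index 1-based position of the segment within the architecture.
#' @return A `segment_spec` object with fields `index`, `kind`, `sequences`
#'   and `length` (`NA` for the variable-length read segment).
#' @examples
#' parse_segment("B:GTA,AAC", 2)
#' parse_segment("F:NNN", 1)
#' @export
parse_segment <- function(spec, index) {
  stopifnot(is.character(spec), length(spec) == 1L)
  spec <- toupper(trimws(spec))
  if (!grepl("^[BFSRP]:", spec)) {
    stop("segment ", index, " ('", spec,
         "'): expected '<K>:<body>' with K in B,F,S,R,P", call. = FALSE)
  }
  kind_letter <- substr(spec, 1L, 1L)
  body <- substr(spec, 3L, nchar(spec))
  if (!nzchar(body)) {
    stop("segment ", index, " ('", spec, "'): empty body", call. = FALSE)
  }
  seqs <- strsplit(body, ",", fixed = TRUE)[[1L]]
  seqs <- seqs[nzchar(seqs)]
  if (length(seqs) == 0L) {
    stop("segment ", index, " ('", spec, "'): empty body", call. = FALSE)
  }
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("segment ", index, " ('", spec, "'): non-ACGTN characters in '",
         seqs[bad][1L], "'", call. = FALSE)
  }
  kind <- c(B = "BARCODE", F = "FINGERPRINT", S = "SPACER",
            R = "READ", P = "PARTIAL")[[kind_letter]]

  switch(kind,
    BARCODE = {
      if (length(unique(nchar(seqs))) != 1L)
        stop("segment ", index, " ('", spec,
             "'): barcode alternatives have unequal lengths", call. = FALSE)
      if (any(grepl("N", seqs, fixed = TRUE)))
        stop("segment ", index, " ('", spec,
             "'): N is not allowed in barcode sequences", call. = FALSE)
    },
    FINGERPRINT = {
      if (length(seqs) != 1L || grepl("[^N]", seqs))
        stop("segment ", index, " ('", spec,
             "'): fingerprint must be a single run of N", call. = FALSE)
    },
    SPACER = {
      if (length(seqs) != 1L)
        stop("segment ", index, " ('", spec,
             "'): spacer takes a single sequence", call. = FALSE)
      if (grepl("N", seqs, fixed = TRUE))
        stop("segment ", index, " ('", spec,
             "'): N is not allowed in a spacer", call. = FALSE)
    },
    READ = {
      if (length(seqs) != 1L || seqs != "N")
        stop("segment ", index, " ('", spec,
             "'): the read segment must be declared as R:N", call. = FALSE)
    },
    PARTIAL = {
      if (length(seqs) != 1L)
        stop("segment ", index, " ('", spec,
             "'): partial adapter takes a single sequence", call. = FALSE)
      if (grepl("N", seqs, fixed = TRUE))
        stop("segment ", index, " ('", spec,
             "'): N is not allowed in a partial adapter", call. = FALSE)
    }
  )
  structure(
    list(index = as.integer(index), kind = kind, sequences = seqs,
         length = if (kind == "READ") NA_integer_ else nchar(seqs[[1L]])),
    class = "segment_spec")
}

#' Parse an ordered list of segment declarations into a read architecture
#'
#' @param specs Character vector of segment declarations in read order,
#'   e.g. `c("B:GTA,AAC", "R:N")`. Exactly one `R:` segment is required.
#' @param name Identifier for the architecture.
#' @return A `read_architecture` object: `segments` (list of
#'   [parse_segment()] results), `total_fingerprint_length`, `name`.
#' @examples
#' parse_architecture(c("F:NNN", "S:T", "B:GACTT", "R:N"))
#' @export
parse_architecture <- function(specs, name = "arch") {
  stopifnot(is.character(specs), length(specs) >= 1L)
  segments <- lapply(seq_along(specs), function(i) parse_segment(specs[[i]], i))
  kinds <- vapply(segments, `[[`, "", "kind")
  n_read <- sum(kinds == "READ")
  if (n_read != 1L) {
    stop("architecture '", name, "': expected exactly one R:N segment, found ",
         n_read, call. = FALSE)
  }
  structure(
    list(segments = segments,
         total_fingerprint_length = sum(vapply(
           segments[kinds == "FINGERPRINT"], `[[`, 0L, "length")),
         name = name),
    class = "read_architecture")
}

#' Format an architecture back into its segment declarations
#'
#' Inverse of [parse_architecture()]: `parse_architecture(format(a))` is
#' structurally identical to `a`.
#' @param x A `read_architecture`.
#' @param ... Unused.
#' @return Character vector of segment declarations.
#' @export
format.read_architecture <- function(x, ...) {
  vapply(x$segments, function(s) {
    paste0(substr(s$kind, 1L, 1L), ":", paste(s$sequences, collapse = ","))
  }, "")
}

#' @export
print.read_architecture <- function(x, ...) {
  cat("read architecture '", x$name, "': ",
      paste(format(x), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' @export
print.segment_spec <- function(x, ...) {
  cat(x$kind, " segment ", x$index, ": ",
      paste(x$sequences, collapse = ","), "\n", sep = "")
  invisible(x)
}

#' Load a library of candidate read architectures from a text file
#'
#' One architecture per line: a name followed by whitespace-separated segment
#' declarations. Blank lines and lines starting with `#` are ignored.
#'
#' @param path Path to the architecture file.
#' @return An `architecture_library`: a named list of `read_architecture`
#'   objects.
#' @seealso [detect_architecture()] to pick the best match for a read set.
#' @export
load_architecture_file <- function(path) {
  if (!file.exists(path)) stop("cannot read architecture file: ", path,
                               call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("architecture file '", path,
                                "' contains no architectures", call. = FALSE)
  archs <- lapply(lines, function(ln) {
    tok <- strsplit(ln, "[ \t]+")[[1L]]
    if (length(tok) < 2L)
      stop("architecture file line '", ln,
           "': expected '<name> <segments...>'", call. = FALSE)
    parse_architecture(tok[-1L], name = tok[[1L]])
  })
  nm <- vapply(archs, `[[`, "", "name")
  if (anyDuplicated(nm))
    stop("duplicate architecture name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  names(archs) <- nm
  structure(archs, class = "architecture_library")
}

#' @export
print.architecture_library <- function(x, ...) {
  cat("architecture library with", length(x), "architecture(s)\n")
  for (a in x) print(a)
  invisible(x)
}

arch_kinds <- function(arch) vapply(arch$segments, `[[`, "", "kind")

# total length of the fixed (non-READ) part of the architecture
arch_fixed_length <- function(arch) {
  k <- arch_kinds(arch)
  sum(vapply(arch$segments[k != "READ"], `[[`, 0L, "length"))
}
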