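# 96-channel trinucleotide machinery.  Channels are ordered by substitution
# block (C>A, C>G, C>T, T>A, T>C, T>G), then 5' base (A,C,G,T), then 3' base
# (A,C,G,T); purine-reference substitutions are folded onto the pyrimidine
# strand by reverse complement before lookup.

sub_blocks <- function() c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
bases <- function() c("A", "C", "G", "T")

#' Canonical channel labels
#'
#' @return character vector of 96 labels like `"A[C>T]G"`, in canonical
#'   order.
#' @export
channel_labels <- function() {
  out <- character(96)
  i <- 1
  for (s in sub_blocks()) for (b5 in bases()) for (b3 in bases()) {
    out[i] <- paste0(b5, "[", s, "]", b3)
    i <- i + 1
  }
  out
}

revcomp <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(strsplit(x, NULL), function(ch) paste(rev(ch), collapse = ""),
                character(1)))
}

#' Trinucleotide channel of a single-base substitution
#'
#' Maps a substitution and its trinucleotide context to the canonical
#' 96-channel index (0-based).  Purine-reference substitutions are
#' reverse-complemented to the pyrimidine strand first.
#'
#' @param ref,alt single reference and alternate bases (vectors allowed).
#' @param context 3-base context string whose middle base equals `ref`.
#' @return integer vector of channel indices in `[0, 95]`.
#' @export
trinucleotide_channel <- function(ref, alt, context) {
  n <- max(length(ref), length(alt), length(context))
  ref <- rep_len(toupper(ref), n)
  alt <- rep_len(toupper(alt), n)
  context <- rep_len(toupper(context), n)
  if (any(!ref %in% bases()) || any(!alt %in% bases()))
    stop("ref and alt must be single A/C/G/T bases (indels have no channel)")
  if (any(ref == alt)) stop("ref and alt must differ")
  if (any(nchar(context) != 3) ||
      any(!unlist(strsplit(context, NULL)) %in% bases()))
    stop("context must be a 3-base A/C/G/T string")
  if (any(substr(context, 2, 2) != ref))
    stop("context middle base must equal ref")
  flip <- ref %in% c("A", "G")
  ref[flip] <- chartr("ACGT", "TGCA", ref[flip])
  alt[flip] <- chartr("ACGT", "TGCA", alt[flip])
  context[flip] <- revcomp(context[flip])
  block <- match(paste0(ref, ">", alt), sub_blocks()) - 1L
  b5 <- match(substr(context, 1, 1), bases()) - 1L
  b3 <- match(substr(context, 3, 3), bases()) - 1L
  as.integer(16L * block + 4L * b5 + b3)
}

#' Build a 96-channel mutation spectrum for one patient
#'
#' Counts all single-base substitutions that carry a trinucleotide context;
#' indels and context-less SNVs are excluded and their number reported.
#'
#' @param variants data.frame of variant calls for one patient with columns
#'   `ref`, `alt` and `trinucleotide_context`.
#' @return list with `patient_id`, `counts` (named integer 96-vector in
#'   canonical channel order) and `n_excluded`.
#' @export
build_spectrum <- function(variants) {
  if (nrow(variants) > 0 && length(unique(variants$patient_id)) > 1)
    stop("build_spectrum expects variants from a single patient")
  counts <- stats::setNames(integer(96), channel_labels())
  pid <- if (nrow(variants) > 0) variants$patient_id[[1]] else NA_character_
  ref <- col_or(variants, "ref", NA_character_)
  alt <- col_or(variants, "alt", NA_character_)
  ctx <- col_or(variants, "trinucleotide_context", NA_character_)
  is_sbs <- !is.na(ref) & !is.na(alt) &
    nchar(ref) == 1 & nchar(alt) == 1 &
    toupper(ref) %in% bases() & toupper(alt) %in% bases()
  has_ctx <- !is.na(ctx) & nzchar(ctx)
  use <- is_sbs & has_ctx
  if (any(use)) {
    idx <- trinucleotide_channel(ref[use], alt[use], ctx[use]) + 1L
    tab <- tabulate(idx, nbins = 96)
    counts[] <- as.integer(tab)
  }
  list(patient_id = pid, counts = counts,
       n_excluded = as.integer(nrow(variants) - sum(use)))
}

#' Synthetic default signature catalogue
#'
#' Four stylised 96-channel profiles for the mutational processes that
#' dominate bladder cancer: two APOBEC cytidine-deaminase signatures
#' (C>T and C>G at TpC sites), C>T transitions at CpG dinucleotides from
#' 5-methylcytosine deamination, and a broad, relatively flat
#' clock-like/NER-deficiency profile associated with ERCC2 mutation.  The
#' profiles are synthetic constructions that concentrate each process's
#' defining channels; they are suitable for simulation and for
#' property-level refitting studies, and any catalogue with the same schema
#' (for example published reference signatures) may be substituted via
#' [read_signature_catalog()].
#'
#' @return a signature catalogue: list with `names`, `profiles` (96 x 4
#'   column-stochastic matrix) and `fuse_groups`
#'   (`list(APOBEC = c("APOBEC_a", "APOBEC_b"))`).
#' @export
synthetic_signature_catalog <- function() {
  lab <- channel_labels()
  prof <- matrix(0, 96, 4, dimnames = list(lab, c("APOBEC_a", "APOBEC_b",
                                                  "ERCC2", "C_T_CpG")))
  # APOBEC_a: C>T at TpC, strongest at TCA/TCT
  prof["T[C>T]A", 1] <- 0.36; prof["T[C>T]T", 1] <- 0.36
  prof["T[C>T]C", 1] <- 0.10; prof["T[C>T]G", 1] <- 0.10
  prof[, 1] <- prof[, 1] + 0.08 / 96
  # APOBEC_b: C>G at TpC
  prof["T[C>G]A", 2] <- 0.38; prof["T[C>G]T", 2] <- 0.38
  prof["T[C>G]C", 2] <- 0.08; prof["T[C>G]G", 2] <- 0.08
  prof[, 2] <- prof[, 2] + 0.08 / 96
  # ERCC2: broad profile, mild enrichment of C>T and T>C blocks
  w <- rep(1, 96)
  w[33:48] <- 2.2   # C>T block
  w[65:80] <- 1.8   # T>C block
  prof[, 3] <- w / sum(w)
  # C_T_CpG: C>T with 3' G
  for (b5 in bases()) prof[paste0(b5, "[C>T]G"), 4] <- 0.23
  prof[, 4] <- prof[, 4] + 0.08 / 96
  prof <- sweep(prof, 2, colSums(prof), "/")
  list(names = colnames(prof), profiles = prof,
       fuse_groups = list(APOBEC = c("APOBEC_a", "APOBEC_b")))
}

#' Read / write a signature catalogue
#'
#' On-disk format: TSV with 96 rows in canonical channel order, a `channel`
#' row-label column and one column per signature.
#'
#' @param path file path.
#' @param fuse_groups optional named list mapping a report label to member
#'   signature names (default fuses `APOBEC_a`/`APOBEC_b` when both exist).
#' @return a signature catalogue list (see
#'   [synthetic_signature_catalog()]).
#' @export
read_signature_catalog <- function(path, fuse_groups = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (names(df)[[1]] != "channel")
    stop("first column of a catalogue file must be 'channel'")
  if (!identical(df$channel, channel_labels()))
    stop("catalogue channels must be the 96 canonical labels in order")
  prof <- as.matrix(df[, -1, drop = FALSE])
  rownames(prof) <- df$channel
  if (is.null(fuse_groups) &&
      all(c("APOBEC_a", "APOBEC_b") %in% colnames(prof)))
    fuse_groups <- list(APOBEC = c("APOBEC_a", "APOBEC_b"))
  cat <- list(names = colnames(prof), profiles = prof,
              fuse_groups = if (is.null(fuse_groups)) list() else fuse_groups)
  validate_catalog(cat)
  cat
}

#' @rdname read_signature_catalog
#' @param catalog a signature catalogue list.
#' @export
write_signature_catalog <- function(catalog, path) {
  validate_catalog(catalog)
  df <- data.frame(channel = channel_labels(), catalog$profiles,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_catalog <- function(cat) {
  stopifnot(is.list(cat), !is.null(cat$profiles), !is.null(cat$names))
  p <- cat$profiles
  if (nrow(p) != 96) stop("signature profiles must have 96 channels")
  if (any(p < 0)) stop("signature profiles must be non-negative")
  if (any(abs(colSums(p) - 1) > 1e-9))
    stop("each signature profile must sum to 1")
  if (anyDuplicated(cat$names)) stop("signature names must be unique")
  for (g in cat$fuse_groups)
    if (!all(g %in% cat$names))
      stop("fuse group member not in catalogue: ",
           paste(setdiff(g, cat$names), collapse = ", "))
  invisible(cat)
}

#' Project a spectrum onto a signature catalogue
#'
#' Solves the non-negative least-squares problem
#' \eqn{\min_{w \ge 0} \| c - P w \|_2} where `c` is the 96-channel count
#' vector and the columns of `P` are the catalogue profiles, then rescales
#' the loadings to sum to the spectrum total so the result reads as
#' attributed mutation counts.  Fused groups (by default the two APOBEC
#' signatures) are reported as the sum of their members' loadings.
#'
#' @param spectrum a spectrum from [build_spectrum()], or a bare 96-vector
#'   of channel counts.
#' @param catalog a signature catalogue (default
#'   [synthetic_signature_catalog()]).
#' @return named numeric vector of attributed counts, one entry per report
#'   label (fused groups replace their members), with attribute `"raw"`
#'   holding the unfused, unrescaled NNLS loadings.
#' @export
project_signatures <- function(spectrum, catalog = synthetic_signature_catalog()) {
  validate_catalog(catalog)
  counts <- if (is.list(spectrum)) spectrum$counts else spectrum
  if (length(counts) != 96) stop("spectrum must have 96 channels")
  if (any(counts < 0)) stop("spectrum counts must be non-negative")
  P <- catalog$profiles
  if (qr(P)$rank < ncol(P))
    warning("signature profiles are linearly dependent; projection is non-unique")
  w <- pracma::lsqnonneg(P, as.numeric(counts))$x
  names(w) <- catalog$names
  total <- sum(counts)
  scaled <- if (sum(w) > 0) w * total / sum(w) else w
  fused <- scaled
  for (lab in names(catalog$fuse_groups)) {
    members <- catalog$fuse_groups[[lab]]
    fused <- c(fused[setdiff(names(fused), members)],
               stats::setNames(sum(scaled[members]), lab))
  }
  # stable report order: fused labels follow the surviving singletons
  structure(fused, raw = w)
}
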