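#' Build a colored karyotype
#'
#' A karyotype is an ordered multiset of chromosomes, each a signed sequence
#' of ancestral segments. A segment carries an ancestral color (the founder
#' protochromosome it descends from), a copy index (incremented by
#' whole-genome duplication) and an orientation. Chromosomes are given as
#' character vectors of colors, optionally signed (`"-A"` for an inverted
#' segment); every segment instance receives its own internal id, so
#' segments with the same color are tracked individually.
#'
#' @param chromosomes list of character vectors of (optionally signed)
#'   colors, e.g. `list(c("A", "A"), c("B", "-C"))`.
#' @param name karyotype name.
#' @return a `karyotype` object.
#' @export
karyotype <- function(chromosomes, name = "karyotype") {
  pk_assert(length(chromosomes) >= 1, "a karyotype needs >= 1 chromosome")
  ids <- 0L
  segs <- list()
  chroms <- lapply(chromosomes, function(ch) {
    pk_assert(length(ch) >= 1, "a chromosome needs >= 1 segment")
    sgn <- ifelse(startsWith(ch, "-"), -1L, 1L)
    col <- sub("^[+-]", "", ch)
    out <- integer(length(ch))
    for (i in seq_along(ch)) {
      ids <<- ids + 1L
      segs[[ids]] <<- list(color = col[i], copy = 1L)
      out[i] <- sgn[i] * ids
    }
    out
  })
  structure(list(name = name, chromosomes = chroms,
                 colors = vapply(segs, `[[`, "", "color"),
                 copies = vapply(segs, `[[`, 0L, "copy")),
            class = "karyotype")
}

#' Number of chromosomes of a karyotype
#' @param k a `karyotype`.
#' @return integer chromosome count `n`.
#' @export
n_chromosomes <- function(k) length(k$chromosomes)

seg_labels <- function(k) paste0(k$colors, ".", k$copies)

chrom_key <- function(x, lbl) {
  fwd <- paste0(ifelse(x > 0, "+", "-"), lbl[abs(x)], collapse = ",")
  y <- -rev(x)
  rev_ <- paste0(ifelse(y > 0, "+", "-"), lbl[abs(y)], collapse = ",")
  if (fwd <= rev_) fwd else rev_
}

#' Canonical key of a karyotype
#'
#' Chromosomes are unordered and have no intrinsic reading direction: each
#' chromosome is read in the lexicographically smaller of its two strands
#' and chromosomes are sorted. Two karyotypes are equal when their
#' canonical keys (over color.copy labels) coincide.
#'
#' @param k a `karyotype`.
#' @return character scalar key.
#' @export
canonical_key <- function(k) {
  lbl <- seg_labels(k)
  paste(sort(vapply(k$chromosomes, chrom_key, "", lbl = lbl)),
        collapse = "|")
}

#' Test canonical equality of two karyotypes
#' @param a,b `karyotype` objects.
#' @return logical.
#' @export
karyotypes_equal <- function(a, b) canonical_key(a) == canonical_key(b)

#' @export
print.karyotype <- function(x, ...) {
  lbl <- seg_labels(x)
  cat(sprintf("<karyotype '%s'> n = %d\n", x$name, n_chromosomes(x)))
  for (i in seq_along(x$chromosomes)) {
    ch <- x$chromosomes[[i]]
    cat(sprintf("  chr%-3d %s\n", i,
                paste0(ifelse(ch > 0, "+", "-"), lbl[abs(ch)],
                       collapse = " ")))
  }
  invisible(x)
}

#' @export
format.karyotype <- function(x, ...) canonical_key(x)

flip_chrom <- function(x) -rev(x)

# ---- event constructors ----------------------------------------------------

#' Karyotype events
#'
#' Constructors for the rearrangement event calculus. The chromosome-count
#' law: whole-genome duplication (WGD) doubles `n`; a fission (Cfis) adds
#' one; a fusion (Cfus, telomeric or centromeric/nested) removes one;
#' inversions, reciprocal translocations and deletions leave `n` unchanged.
#'
#' * `ev_wgd()` duplicates every chromosome, incrementing the copy index of
#'   the new copies.
#' * `ev_fission(chr, pos)` splits chromosome `chr` after segment `pos`
#'   (the first part stays in place, the second is appended).
#' * `ev_fusion(chr1, chr2, flip1, flip2)` joins two chromosomes end to end
#'   (telomeric fusion, TCF); the flips select which telomeres join.
#' * `ev_fusion_nested(host, chr2, pos, flip2)` inserts `chr2` into `host`
#'   after segment `pos` (centromeric/nested fusion, CCF).
#' * `ev_inversion(chr, from, to)` reverses the segment run `from..to`.
#' * `ev_translocation(chr1, pos1, chr2, pos2)` reciprocally exchanges the
#'   tails after `pos1`/`pos2` (positions may be 0 or the chromosome
#'   length, provided no empty chromosome results).
#' * `ev_deletion(chr, from, to)` removes segments `from..to` (at least one
#'   segment must remain).
#'
#' @param chr,chr1,chr2,host chromosome indices.
#' @param pos,pos1,pos2 breakpoint positions (after the given segment).
#' @param from,to segment range bounds.
#' @param flip1,flip2 reverse an operand before joining.
#' @return an event object for [apply_event()] / [replay()].
#' @name events
NULL

#' @rdname events
#' @export
ev_wgd <- function() structure(list(kind = "wgd"), class = "pk_event")

#' @rdname events
#' @export
ev_fission <- function(chr, pos)
  structure(list(kind = "fission", chr = chr, pos = pos),
            class = "pk_event")

#' @rdname events
#' @export
ev_fusion <- function(chr1, chr2, flip1 = FALSE, flip2 = FALSE)
  structure(list(kind = "fusion_tcf", chr1 = chr1, chr2 = chr2,
                 flip1 = flip1, flip2 = flip2), class = "pk_event")

#' @rdname events
#' @export
ev_fusion_nested <- function(host, chr2, pos, flip2 = FALSE)
  structure(list(kind = "fusion_ccf", chr1 = host, chr2 = chr2,
                 pos = pos, flip2 = flip2), class = "pk_event")

#' @rdname events
#' @export
ev_inversion <- function(chr, from, to)
  structure(list(kind = "inversion", chr = chr, from = from, to = to),
            class = "pk_event")

#' @rdname events
#' @export
ev_translocation <- function(chr1, pos1, chr2, pos2)
  structure(list(kind = "translocation", chr1 = chr1, pos1 = pos1,
                 chr2 = chr2, pos2 = pos2), class = "pk_event")

#' @rdname events
#' @export
ev_deletion <- function(chr, from, to)
  structure(list(kind = "deletion", chr = chr, from = from, to = to),
            class = "pk_event")

check_chr <- function(k, i) {
  pk_assert(is.numeric(i) && i >= 1 && i <= n_chromosomes(k),
            "chromosome index %s outside karyotype (n = %d)",
            toString(i), n_chromosomes(k))
}

#' Apply one event to a karyotype
#'
#' Enforces the count law (WGD: n to 2n; fission: n+1; fusion: n-1;
#' inversion/translocation/deletion: n unchanged) and conserves the
#' multiset of (color, copy) segments except where the event defines
#' otherwise (WGD doubles it, deletion removes part of it).
#'
#' @param k a `karyotype`.
#' @param event an event from the [events] constructors.
#' @return the derived `karyotype`.
#' @export
apply_event <- function(k, event) {
  ch <- k$chromosomes
  switch(
    event$kind,
    wgd = {
      nseg <- length(k$colors)
      bump <- max(k$copies)
      k$colors <- c(k$colors, k$colors)
      k$copies <- c(k$copies, k$copies + bump)
      dup <- lapply(ch, function(x) sign(x) * (abs(x) + nseg))
      k$chromosomes <- c(ch, dup)
      k
    },
    fission = {
      check_chr(k, event$chr)
      x <- ch[[event$chr]]
      pk_assert(event$pos >= 1 && event$pos < length(x),
                "fission breakpoint %s outside chromosome of %d segments",
                toString(event$pos), length(x))
      ch[[event$chr]] <- x[seq_len(event$pos)]
      ch[[length(ch) + 1L]] <- x[(event$pos + 1L):length(x)]
      k$chromosomes <- ch
      k
    },
    fusion_tcf = {
      check_chr(k, event$chr1); check_chr(k, event$chr2)
      pk_assert(event$chr1 != event$chr2,
                "cannot fuse a chromosome with itself")
      a <- ch[[event$chr1]]; b <- ch[[event$chr2]]
      if (isTRUE(event$flip1)) a <- flip_chrom(a)
      if (isTRUE(event$flip2)) b <- flip_chrom(b)
      ch[[event$chr1]] <- c(a, b)
      ch[[event$chr2]] <- NULL
      k$chromosomes <- ch
      k
    },
    fusion_ccf = {
      check_chr(k, event$chr1); check_chr(k, event$chr2)
      pk_assert(event$chr1 != event$chr2,
                "cannot fuse a chromosome with itself")
      host <- ch[[event$chr1]]; b <- ch[[event$chr2]]
      pk_assert(event$pos >= 1 && event$pos < length(host),
                "nested-fusion insertion point must be internal to the host")
      if (isTRUE(event$flip2)) b <- flip_chrom(b)
      ch[[event$chr1]] <- c(host[seq_len(event$pos)], b,
                            host[(event$pos + 1L):length(host)])
      ch[[event$chr2]] <- NULL
      k$chromosomes <- ch
      k
    },
    inversion = {
      check_chr(k, event$chr)
      x <- ch[[event$chr]]
      pk_assert(event$from >= 1 && event$to <= length(x) &&
                  event$from <= event$to,
                "inversion range outside chromosome")
      x[event$from:event$to] <- flip_chrom(x[event$from:event$to])
      ch[[event$chr]] <- x
      k$chromosomes <- ch
      k
    },
    translocation = {
      check_chr(k, event$chr1); check_chr(k, event$chr2)
      pk_assert(event$chr1 != event$chr2,
                "translocation needs two distinct chromosomes")
      a <- ch[[event$chr1]]; b <- ch[[event$chr2]]
      pk_assert(event$pos1 >= 0 && event$pos1 <= length(a) &&
                  event$pos2 >= 0 && event$pos2 <= length(b),
                "translocation breakpoint outside chromosome")
      new1 <- c(a[seq_len(event$pos1)], b[seq_len(length(b) - event$pos2) +
                                            event$pos2])
      new2 <- c(b[seq_len(event$pos2)], a[seq_len(length(a) - event$pos1) +
                                            event$pos1])
      pk_assert(length(new1) >= 1 && length(new2) >= 1,
                "translocation would create an empty chromosome")
      ch[[event$chr1]] <- new1
      ch[[event$chr2]] <- new2
      k$chromosomes <- ch
      k
    },
    deletion = {
      check_chr(k, event$chr)
      x <- ch[[event$chr]]
      pk_assert(event$from >= 1 && event$to <= length(x) &&
                  event$from <= event$to, "deletion range outside chromosome")
      pk_assert(event$to - event$from + 1 < length(x),
                "deletion may not remove a whole chromosome")
      ch[[event$chr]] <- x[-(event$from:event$to)]
      k$chromosomes <- ch
      k
    },
    pk_stop("unknown event kind '%s'", event$kind))
}

#' Replay an event list on a karyotype
#'
#' Left fold of [apply_event()]; errors are re-signalled with the failing
#' step index. The result records the per-step chromosome-count trace.
#'
#' @param start a `karyotype`.
#' @param events list of events.
#' @return a `pk_scenario` object: `start`, `events`, `end`, and `trace`
#'   (tibble `step`, `kind`, `n`).
#' @export
replay <- function(start, events) {
  k <- start
  n_trace <- integer(length(events))
  for (i in seq_along(events)) {
    k <- tryCatch(apply_event(k, events[[i]]),
                  error = function(e)
                    pk_stop("event %d (%s) failed: %s", i,
                            events[[i]]$kind, conditionMessage(e)))
    n_trace[i] <- n_chromosomes(k)
  }
  structure(list(start = start, events = events, end = k,
                 trace = tibble(step = seq_along(events),
                                kind = vapply(events, `[[`, "", "kind"),
                                n = n_trace)),
            class = "pk_scenario")
}

#' @export
print.pk_scenario <- function(x, ...) {
  cat(sprintf("<scenario> %d events: n = %d -> %d\n", length(x$events),
              n_chromosomes(x$start), n_chromosomes(x$end)))
  invisible(x)
}

#' Classify a fusion product as telomeric (TCF) or centromeric (CCF)
#'
#' Given the color layouts of the two fused chromosomes and of the fusion
#' product, the fusion is telomeric (TCF, end-to-end) when the product
#' reads as the concatenation of the parents (pattern `A..A B..B`), and
#' centromeric/nested (CCF, reported in the literature as NCF) when one
#' parent lies strictly inside the other (pattern `A..B..A`). A CCF
#' expands to 1 fission + 2 fusions of elementary steps. Layouts matching
#' neither pattern give mode `"complex"`.
#'
#' @param pre1,pre2 character color vectors of the two fused chromosomes.
#' @param post character color vector of the fusion product.
#' @return list with `mode` (`"TCF"`, `"CCF"` or `"complex"`) and
#'   `elementary` (named count of elementary Cfis/Cfus steps).
#' @export
classify_fusion <- function(pre1, pre2, post) {
  strip <- function(x) sub("^[+-]", "", x)
  pre1 <- strip(pre1); pre2 <- strip(pre2); post <- strip(post)
  complex_out <- list(mode = "complex",
                      elementary = c(Cfis = NA_integer_, Cfus = NA_integer_))
  if (length(post) != length(pre1) + length(pre2)) return(complex_out)
  if (!identical(sort(post), sort(c(pre1, pre2)))) return(complex_out)
  if (length(intersect(unique(pre1), unique(pre2))) > 0) return(complex_out)
  parent <- ifelse(post %in% pre1, 1L, 2L)
  runs <- rle(parent)$values
  if (length(runs) <= 2)
    return(list(mode = "TCF", elementary = c(Cfis = 0L, Cfus = 1L)))
  if (length(runs) == 3 && runs[1] == runs[3])
    return(list(mode = "CCF", elementary = c(Cfis = 1L, Cfus = 2L)))
  complex_out
}

#' Chromosome-count arithmetic along an event series
#'
#' Pure count arithmetic without segment tracking: WGD doubles the running
#' chromosome number (a genome triplication, `"wgt"`, triples it), `"+k"`
#' applies k fissions, `"-k"` k fusions. Matches the `n` trace of a
#' segment-level [replay()] of any consistent scenario.
#'
#' @param n0 starting chromosome number.
#' @param steps character vector of steps (`"wgd"`, `"wgt"`, `"+4"`,
#'   `"-15"`) or numeric elements (positive = fissions, negative = fusions).
#' @return tibble `step`, `op`, `n` (running chromosome number); the final
#'   `n` is the last row.
#' @export
count_trace <- function(n0, steps) {
  pk_assert(n0 >= 1, "starting chromosome number must be >= 1")
  if (length(steps) == 0)
    return(tibble(step = integer(), op = character(), n = integer()))
  n <- n0
  out <- vector("list", length(steps))
  for (i in seq_along(steps)) {
    s <- steps[[i]]
    if (is.numeric(s)) s <- sprintf("%+d", as.integer(s))
    n <- switch(substr(s, 1, 1),
                w = if (s == "wgd") 2 * n
                else if (s == "wgt") 3 * n
                else pk_stop("unknown step '%s'", s),
                "+" = n + as.integer(substring(s, 2)),
                "-" = n - as.integer(substring(s, 2)),
                pk_stop("unknown step '%s'", s))
    pk_assert(n >= 1, "chromosome number fell to %d at step %d", n, i)
    out[[i]] <- tibble(step = i, op = s, n = n)
  }
  bind_rows(out) %||% tibble(step = integer(), op = character(),
                             n = integer())
}

#' Final chromosome number of a count trace
#' @param n0 starting chromosome number.
#' @param steps see [count_trace()].
#' @return integer final `n`.
#' @export
count_final <- function(n0, steps) {
  tr <- count_trace(n0, steps)
  if (nrow(tr) == 0) n0 else tr$n[nrow(tr)]
}
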