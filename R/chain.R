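#' Liftover chains between a base and a custom coordinate system
#'
#' A chain records, per sequence, the ordered ungapped alignment blocks
#' between the base ("reference") genome and an edited custom genome.
#' Blocks are stored internally in 0-based half-open coordinates as
#' `(ref_start, custom_start, length)`; they are non-overlapping and
#' strictly increasing on both sides. On disk the UCSC chain format is used
#' (target = base genome, query = custom genome), so external liftOver
#' implementations can consume the files.
#'
#' @param entries List, one element per sequence, each a list with
#'   `ref_name`, `ref_len`, `custom_name`, `custom_len` and a `blocks`
#'   data.frame with columns `ref_start`, `custom_start`, `length`.
#' @return Object of class `liftover_chain` (list keyed by `ref_name`).
#' @export
liftover_chain <- function(entries) {
  stopifnot(is.list(entries))
  for (e in entries) {
    stopifnot(all(c("ref_name", "ref_len", "custom_name", "custom_len",
                    "blocks") %in% names(e)))
    b <- e$blocks
    stopifnot(is.data.frame(b),
              all(c("ref_start", "custom_start", "length") %in% names(b)))
    if (nrow(b)) {
      if (any(b$length < 1L)) stop("zero-length chain block")
      re <- b$ref_start + b$length
      ce <- b$custom_start + b$length
      if (any(b$ref_start < 0L) || any(b$custom_start < 0L))
        stop("negative block start")
      if (nrow(b) > 1L) {
        dr <- b$ref_start[-1L] - re[-nrow(b)]
        dc <- b$custom_start[-1L] - ce[-nrow(b)]
        if (any(dr < 0L) || any(dc < 0L))
          stop("chain blocks overlap or are not increasing")
        if (any(dr == 0L & dc == 0L))
          stop("adjacent chain blocks with no gap on either side")
      }
      if (re[nrow(b)] > e$ref_len || ce[nrow(b)] > e$custom_len)
        stop("chain blocks exceed sequence length")
    }
  }
  names(entries) <- vapply(entries, `[[`, character(1L), "ref_name")
  structure(entries, class = "liftover_chain")
}

#' @exportS3Method base::print
print.liftover_chain <- function(x, ...) {
  cat("liftover_chain:", length(x), "sequence(s)\n")
  for (e in x)
    cat(" ", e$ref_name, ":", nrow(e$blocks), "block(s),",
        e$ref_len, "->", e$custom_len, "bp\n")
  invisible(x)
}

# identity chain for an unedited genome
identity_chain <- function(g) {
  liftover_chain(lapply(names(g), function(nm) {
    L <- nchar(g[[nm]])
    list(ref_name = nm, ref_len = L, custom_name = nm, custom_len = L,
         blocks = data.frame(ref_start = 0L, custom_start = 0L, length = L))
  }))
}

#' Write / read UCSC chain files
#'
#' Serialization is deterministic: chain ids are sequential and the score
#' field is the sum of block lengths, so identical chains yield
#' byte-identical files.
#'
#' @param chain A [liftover_chain()].
#' @param path File path.
#' @return `write_chain` invisibly returns `path`; `read_chain` returns a
#'   [liftover_chain()].
#' @export
write_chain <- function(chain, path) {
  stopifnot(inherits(chain, "liftover_chain"))
  out <- character(0)
  cid <- 0L
  for (e in chain) {
    b <- e$blocks
    if (nrow(b) == 0L) next
    cid <- cid + 1L
    t_start <- b$ref_start[1L]
    t_end <- b$ref_start[nrow(b)] + b$length[nrow(b)]
    q_start <- b$custom_start[1L]
    q_end <- b$custom_start[nrow(b)] + b$length[nrow(b)]
    hdr <- paste("chain", sum(b$length), e$ref_name, e$ref_len, "+",
                 t_start, t_end, e$custom_name, e$custom_len, "+",
                 q_start, q_end, cid)
    if (nrow(b) > 1L) {
      dt <- b$ref_start[-1L] - (b$ref_start[-nrow(b)] + b$length[-nrow(b)])
      dq <- b$custom_start[-1L] - (b$custom_start[-nrow(b)] + b$length[-nrow(b)])
      body <- c(paste(b$length[-nrow(b)], dt, dq, sep = "\t"),
                as.character(b$length[nrow(b)]))
    } else {
      body <- as.character(b$length)
    }
    out <- c(out, hdr, body, "")
  }
  writeLines(out, path)
  invisible(path)
}

#' @rdname write_chain
#' @export
read_chain <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  entries <- list()
  i <- 1L
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") { i <- i + 1L; next }
    f <- strsplit(ln, "\\s+")[[1L]]
    if (f[1L] != "chain" || length(f) < 12L)
      stop("malformed chain header at line ", i)
    if (f[5L] != "+" || f[10L] != "+")
      stop("only + strands are supported (line ", i, ")")
    ref_name <- f[3L]; ref_len <- as.integer(f[4L])
    t_start <- as.integer(f[6L]); t_end <- as.integer(f[7L])
    custom_name <- f[8L]; custom_len <- as.integer(f[9L])
    q_start <- as.integer(f[11L]); q_end <- as.integer(f[12L])
    sizes <- integer(0); dts <- integer(0); dqs <- integer(0)
    i <- i + 1L
    repeat {
      if (i > length(lines)) stop("truncated chain block list")
      bl <- trimws(lines[i])
      if (bl == "") stop("blank line inside chain at line ", i)
      bf <- as.integer(strsplit(bl, "\\s+")[[1L]])
      if (length(bf) == 1L) {
        sizes <- c(sizes, bf); i <- i + 1L; break
      } else if (length(bf) == 3L) {
        sizes <- c(sizes, bf[1L]); dts <- c(dts, bf[2L]); dqs <- c(dqs, bf[3L])
        i <- i + 1L
      } else stop("malformed chain block line at line ", i)
    }
    rs <- t_start + cumsum(c(0L, sizes[-length(sizes)] + dts))
    cs <- q_start + cumsum(c(0L, sizes[-length(sizes)] + dqs))
    if (rs[length(rs)] + sizes[length(sizes)] != t_end ||
        cs[length(cs)] + sizes[length(sizes)] != q_end)
      stop("chain block arithmetic does not match header spans for ", ref_name)
    entries[[length(entries) + 1L]] <-
      list(ref_name = ref_name, ref_len = ref_len,
           custom_name = custom_name, custom_len = custom_len,
           blocks = data.frame(ref_start = as.integer(rs),
                               custom_start = as.integer(cs),
                               length = as.integer(sizes)))
  }
  liftover_chain(entries)
}

#' Lift positions through a chain
#'
#' Positions inside an alignment block map affinely onto the other
#' coordinate system; positions falling in a source-side gap (bases deleted
#' going forward, or inserted bases when lifting in reverse) are unmapped
#' and returned as `NA`.
#'
#' @param chain A [liftover_chain()].
#' @param chrom Sequence name (single string).
#' @param pos Integer vector of 1-based positions in the source system.
#' @param direction `"forward"` (base -> custom) or `"reverse"`
#'   (custom -> base).
#' @return Integer vector of lifted 1-based positions, `NA` where unmapped.
#'   `lift_position` is the scalar convenience form.
#' @export
lift_positions <- function(chain, chrom, pos,
                           direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  stopifnot(inherits(chain, "liftover_chain"))
  e <- chain[[chrom]]
  if (is.null(e)) stop("sequence not in chain: ", chrom)
  src_len <- if (direction == "forward") e$ref_len else e$custom_len
  pos <- as.integer(pos)
  if (any(pos < 1L | pos > src_len))
    stop("position out of bounds for ", chrom)
  b <- e$blocks
  if (nrow(b) == 0L) return(rep(NA_integer_, length(pos)))
  if (direction == "forward") {
    src_start <- b$ref_start; dst_start <- b$custom_start
  } else {
    src_start <- b$custom_start; dst_start <- b$ref_start
  }
  p0 <- pos - 1L
  idx <- findInterval(p0, src_start)
  out <- rep(NA_integer_, length(pos))
  hit <- idx >= 1L & p0 < src_start[pmax(idx, 1L)] + b$length[pmax(idx, 1L)]
  out[hit] <- dst_start[idx[hit]] + (p0[hit] - src_start[idx[hit]]) + 1L
  out
}

#' @rdname lift_positions
#' @export
lift_position <- function(chain, chrom, pos,
                          direction = c("forward", "reverse")) {
  stopifnot(length(pos) == 1L)
  lift_positions(chain, chrom, pos, direction)
}
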