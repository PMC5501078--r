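# Shared helpers: substitution classes, trinucleotide contexts, misc checks.

BASES <- c("A", "C", "G", "T")

# Pyrimidine-referenced substitution classes in the conventional order.
SUB_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

comp_base <- function(x) {
  chartr("ACGTN", "TGCAN", x)
}

revcomp <- function(x) {
  vapply(strsplit(comp_base(x), "", fixed = TRUE),
         function(b) paste(rev(b), collapse = ""), character(1))
}

#' The 96 trinucleotide mutation channels
#'
#' Channel labels in lexicographic pyrimidine order, e.g. `"A[C>A]A"`:
#' substitution classes `C>A, C>G, C>T, T>A, T>C, T>G`, each with the 16
#' combinations of 5' and 3' flanking base.
#'
#' @return Character vector of length 96.
#' @export
context_channels <- function() {
  out <- character(0)
  for (cls in SUB_CLASSES) {
    for (p5 in BASES) {
      for (p3 in BASES) {
        out <- c(out, paste0(p5, "[", cls, "]", p3))
      }
    }
  }
  out
}

# The 32 pyrimidine-centered trinucleotides (center C or T).
pyrimidine_trinucs <- function() {
  out <- character(0)
  for (center in c("C", "T")) {
    for (p5 in BASES) {
      for (p3 in BASES) {
        out <- c(out, paste0(p5, center, p3))
      }
    }
  }
  out
}

# Collapse a trinucleotide to its pyrimidine-centered representative.
collapse_trinuc <- function(tri) {
  center <- substr(tri, 2, 2)
  flip <- center %in% c("A", "G")
  tri[flip] <- revcomp(tri[flip])
  tri
}

# Decompose a channel label into (class, trinucleotide around the ref base).
channel_parts <- function(channel) {
  p5 <- substr(channel, 1, 1)
  ref <- substr(channel, 3, 3)
  alt <- substr(channel, 5, 5)
  p3 <- substr(channel, 7, 7)
  list(p5 = p5, ref = ref, alt = alt, p3 = p3,
       class = paste0(ref, ">", alt), trinuc = paste0(p5, ref, p3))
}

# Map an observed SNV (ref, alt, 5'/3' flanks on the forward strand) to its
# pyrimidine-referenced channel label.
snv_channel <- function(ref, alt, p5, p3) {
  stopifnot(length(ref) == length(alt))
  flip <- ref %in% c("A", "G")
  r <- ifelse(flip, comp_base(ref), ref)
  a <- ifelse(flip, comp_base(alt), alt)
  f5 <- ifelse(flip, comp_base(p3), p5)
  f3 <- ifelse(flip, comp_base(p5), p3)
  paste0(f5, "[", r, ">", a, "]", f3)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_named <- function(class, msg, ...) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

assert_that <- function(ok, msg, ...) {
  if (!isTRUE(ok)) stop(sprintf(msg, ...), call. = FALSE)
  invisible(TRUE)
}

# Deterministic child seed from a base seed and a stream label (< 2^31).
child_seed <- function(seed, stream) {
  s <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  (as.integer(seed) %% 1000003L) * 1009L + s %% 100000L
}
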