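# internal helpers shared across modules

BASES <- c("A", "C", "G", "T")

# evaluate expr under a temporary RNG state seeded with `seed`
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# derive a child seed < 2^31 from a base seed and a stream label
childSeed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) + 97L * sum(utf8ToInt(as.character(stream)))) %% 2147483647L
}

randomDNA <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  base::paste(sample(BASES, n, replace = TRUE, prob = p), collapse = "")
}

# substitute k distinct positions of a DNA string with a different base
mutatePositions <- function(seq, k) {
  if (k == 0L) return(seq)
  ch <- strsplit(seq, "")[[1]]
  pos <- sample(seq_along(ch), k)
  for (p in pos) ch[p] <- sample(setdiff(BASES, ch[p]), 1)
  base::paste(ch, collapse = "")
}

# per-base substitutions at rate r; returns list(seq, n)
mutateAtRate <- function(seq, rate) {
  if (rate <= 0) return(list(seq = seq, n = 0L))
  ch <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(ch)) < rate)
  for (p in hit) ch[p] <- sample(setdiff(BASES, ch[p]), 1)
  list(seq = base::paste(ch, collapse = ""), n = length(hit))
}

revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# codon-table translation; ambiguous codons (e.g. containing N) become "X"
translateDNA <- function(nt) {
  if (nchar(nt) < 3L) return("")
  n3 <- 3L * (nchar(nt) %/% 3L)
  starts <- seq.int(1L, n3, by = 3L)
  aa <- unname(Biostrings::GENETIC_CODE[substring(nt, starts, starts + 2L)])
  aa[is.na(aa)] <- "X"
  base::paste(aa, collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
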