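# Internal helpers shared across modules.

# Run code with a private RNG stream; the caller's .Random.seed is
# untouched, and identical (seed, code) always yields identical draws.
withSeed <- function(seed, code) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
        stop("'seed' must be a single integer")
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    force(code)
}

# Reverse complement for plain character vectors (DNA alphabet).
revComp <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Map RNA to DNA alphabet and uppercase; used when loading catalogs so
# that all matching happens in one alphabet.
normalizeDna <- function(x) {
    chartr("uU", "TT", toupper(x))
}

# Draw a random DNA string of length n with the given GC fraction.
randomDna <- function(n, gc = 0.5) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = "")
}

# Parse a dot-bracket string into a partner vector: partner[i] is the
# 1-based index paired with i, or NA when i is unpaired. Errors on
# unbalanced brackets.
pairTable <- function(structure) {
    ch <- strsplit(structure, "", fixed = TRUE)[[1L]]
    partner <- rep(NA_integer_, length(ch))
    stack <- integer(0)
    for (i in seq_along(ch)) {
        if (ch[i] == "(") {
            stack <- c(stack, i)
        } else if (ch[i] == ")") {
            if (length(stack) == 0L) stop("unbalanced dot-bracket string")
            j <- stack[length(stack)]
            stack <- stack[-length(stack)]
            partner[j] <- i
            partner[i] <- j
        } else if (ch[i] != ".") {
            stop("invalid character in dot-bracket string: '", ch[i], "'")
        }
    }
    if (length(stack) > 0L) stop("unbalanced dot-bracket string")
    partner
}

# 2-decimal percentage as used in category tables.
pct2 <- function(x, total) {
    if (total == 0) return(rep(0, length(x)))
    round(100 * x / total, 2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
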