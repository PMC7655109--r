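# Shared internal helpers.

#' @keywords internal
"_PACKAGE"

# Residue names recognized as water across common force-field conventions.
.water_resnames <- c("HOH", "WAT", "TIP3", "SOL", "TIP4", "SPC", "T3P")

# Monatomic ion residue names stripped before pore profiling.
.ion_resnames <- c("NA", "CL", "K", "MG", "CA", "ZN", "SOD", "CLA", "POT")

.is_water <- function(resname) toupper(resname) %in% .water_resnames

# Run `expr` with a local RNG state seeded from `seed`; the caller's
# .Random.seed is untouched so analysis functions are reproducible without
# clobbering the session RNG.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

# Euclidean norm / squared distances without recycling surprises.
.vnorm <- function(v) sqrt(sum(v * v))

.unit <- function(v) {
  n <- .vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

# Pairwise distance matrix between two n x 3 coordinate matrices.
.cross_dist <- function(a, b) {
  a <- matrix(a, ncol = 3L)
  b <- matrix(b, ncol = 3L)
  a2 <- rowSums(a^2)
  b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

.cross3 <- function(a, b) {
  c(
    a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1]
  )
}

# Format a residue identifier for messages.
.res_label <- function(chain, resno, icode = "") {
  paste0(chain, ":", resno, ifelse(nzchar(icode), icode, ""))
}
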