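## Shared builders and independent oracles for the test suite. Expensive
## phantoms are built once per session and cached.

.cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.cache[[key]])) .cache[[key]] <- builder()
  .cache[[key]]
}

## 1 x 1 x n homogeneous (or layered) conducting bar with current injected
## uniformly over the end faces; returns system, rhs and montage-like object
bar_problem <- function(n = 10L, spacing = 2, sigma = c(bar = 1),
                        labels = rep(1L, n), current = 1) {
  ph <- voxel_phantom(array(as.integer(labels), c(1L, 1L, n)), spacing,
                      c(0, 0, 0), names(sigma))
  sys <- assemble_stiffness(ph, sigma)
  nd <- dim(ph$labels) + 1L
  nid <- function(i, j, k) 1L + i + nd[1] * (j + nd[2] * k)
  g <- expand.grid(i = 0:1, j = 0:1)
  endA <- nid(g$i, g$j, 0L)
  endB <- nid(g$i, g$j, n)
  mont <- structure(list(
    name = "bar", mode = "neumann", current_A = current,
    patches = list(list(contact_nodes = endA,
                        contact_node_area_mm2 = rep(spacing^2 / 4, 4)),
                   list(contact_nodes = endB,
                        contact_node_area_mm2 = rep(spacing^2 / 4, 4)))),
    class = "montage_spec")
  list(phantom = ph, system = sys, montage = mont,
       rhs = build_rhs_neumann(sys, mont))
}

## default detailed head at 4 mm (coarse desk resolution), no torso
head4 <- function() cached("head4", function()
  default_head_phantom("model2", spacing_mm = 4, torso = FALSE))

## same with torso (for rS montages)
head4t <- function() cached("head4t", function()
  default_head_phantom("model2", spacing_mm = 4, torso = TRUE))

## detailed head at 2 mm, no torso (montage-geometry checks)
head2 <- function() cached("head2", function()
  default_head_phantom("model2", spacing_mm = 2, torso = FALSE))

## deterministic-staircase quantization law (independent closed form)
staircase_law <- function(theta) pmax(50, 25 * ceiling(theta / 25))

## mean of a truncated normal (closed form)
truncnorm_mean <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd; b <- (hi - mu) / sd
  mu + sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
}

## independent permutation enumerator (lexicographic successor algorithm,
## distinct from the package's recursive generator)
next_permutation <- function(p) {
  n <- length(p)
  i <- n - 1L
  while (i >= 1L && p[i] >= p[i + 1L]) i <- i - 1L
  if (i < 1L) return(NULL)
  j <- n
  while (p[j] <= p[i]) j <- j - 1L
  tmp <- p[i]; p[i] <- p[j]; p[j] <- tmp
  p[(i + 1L):n] <- rev(p[(i + 1L):n])
  p
}

all_permutations_lex <- function(n) {
  p <- seq_len(n)
  out <- list(p)
  repeat {
    p <- next_permutation(p)
    if (is.null(p)) break
    out[[length(out) + 1L]] <- p
  }
  do.call(rbind, out)
}
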