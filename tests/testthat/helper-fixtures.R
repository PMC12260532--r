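# Fixture builders and independent oracles, all generated in code.

AA <- foldevo:::AA_ALPHABET

# textbook ideal alpha-helix CA trace (radius 2.3 A, rise 1.5 A, 100 deg)
ideal_helix_ca <- function(n, radius = 2.3, rise = 1.5, turn = 100) {
  th <- seq_len(n) * turn * pi / 180
  cbind(radius * cos(th), radius * sin(th), seq_len(n) * rise)
}

# extended ideal strand CA trace (rise 3.3 A with alternating pleat)
ideal_strand_ca <- function(n, rise = 3.3, wobble = 0.8) {
  cbind(seq_len(n) * rise, wobble * (-1)^(seq_len(n)), rep(0, n))
}

# random-walk coil CA trace (step 3.8 A)
coil_ca <- function(n, step = 3.8) {
  d <- matrix(rnorm(3 * n), n, 3)
  d <- d / sqrt(rowSums(d^2))
  apply(d * step, 2, cumsum)
}

# StructureModel from a CA trace (N/C offset along the chain, CB at CA
# unless given); residues default to a poly-alanine-like random string
model_from_ca <- function(ca, plddt = NULL, ptm = 0.5, residues = NULL,
                          chain = NULL, cb = NULL) {
  n <- nrow(ca)
  if (is.null(residues)) residues <- sample(AA, n, replace = TRUE)
  if (is.null(plddt)) plddt <- rep(0.9, n)
  if (is.null(chain)) chain <- rep("A", n)
  if (is.null(cb)) cb <- ca
  d <- if (n == 1L) matrix(c(1, 0, 0), 1, 3)
       else rbind(ca[2, ] - ca[1, ], diff(ca))
  d <- d / sqrt(rowSums(d^2))
  new("StructureModel", residues = residues, chain = chain,
      n = ca - 1.46 * d, ca = ca, c = ca + 1.52 * d,
      cb = cb, plddt = plddt, ptm = ptm)
}

# random single-chain fixture with scattered CB positions
random_model <- function(n, spread = 8) {
  ca <- matrix(rnorm(3 * n, sd = spread), n, 3)
  model_from_ca(ca, plddt = runif(n), ptm = runif(1))
}

# exhaustive O(n^2) contact-density oracle (independent double loop)
cd_oracle <- function(cb, plddt, distCutoff = 6, sepCutoff = 5,
                      plddtCutoff = 0.5) {
  n <- nrow(cb)
  count <- 0L
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    if (j - i <= sepCutoff) next
    if (plddt[i] <= plddtCutoff || plddt[j] <= plddtCutoff) next
    if (sqrt(sum((cb[i, ] - cb[j, ])^2)) < distCutoff) count <- count + 1L
  }
  count / n
}

# exhaustive inter-chain oracle
interface_oracle <- function(model, evolving = "A", distCutoff = 6,
                             plddtCutoff = 0.5) {
  a <- which(model@chain == evolving)
  b <- which(model@chain != evolving)
  pairs <- 0L
  iface <- integer(0)
  for (i in a) for (j in b) {
    if (model@plddt[i] <= plddtCutoff || model@plddt[j] <= plddtCutoff) next
    if (sqrt(sum((model@cb[i, ] - model@cb[j, ])^2)) < distCutoff) {
      pairs <- pairs + 1L
      iface <- union(iface, c(i, j))
    }
  }
  list(iplddt = if (length(iface)) mean(model@plddt[iface]) else 0,
       icd = pairs / length(a))
}

# small run used by several lineage/engine tests
small_run <- function(seed, popSize = 6L, gens = 10L, mode = "PROPORTIONAL",
                      dict = evolutionaryDictionary(), founderLength = 24L) {
  runSimulation(runConfig(popSize = popSize, founderLength = founderLength,
                          dictionary = dict,
                          selection = selectionConfig(mode),
                          maxGenerations = gens,
                          plddtStop = 1, ptmStop = 1, seed = seed))
}

# replay a lineage's events from the founder, independent of the engine
replay_lineage <- function(lin) {
  s <- lin$path$residues[1]
  for (ev in lin$events) s <- applyMutation(s, ev)
  s
}
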