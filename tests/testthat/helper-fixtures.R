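# Shared fixtures, generated once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name) {
  if (!is.null(.fixtures[[name]])) return(.fixtures[[name]])
  .fixtures[[name]] <- switch(
    name,
    # default bud phantom, 15 sections
    bud15 = generateStack(phantomSpec(nSections = 15)),
    # same geometry, noise-free (pixel-exact colour tests)
    bud9clean = generateStack(phantomSpec(nSections = 9, noiseSd = 0)),
    # spherical rudiment for volumetry oracles
    sphere21 = generateStack(phantomSpec(semiAxes = c(50, 50, 50),
                                         nSections = 21, noiseSd = 0)),
    stop("unknown fixture ", name))
  .fixtures[[name]]
}

# central-section index helpers
centralSection <- function(ph) {
  which(vapply(ph$truth@annotations,
               function(a) !is.null(a) && a@isCentralSection, logical(1)))[1]
}

sectionImage <- function(ph, i) ph$images[[match(i, ph$truth@keptSections)]]

# digital sphere in a 3D logical array (continuous center, physical radius)
sphereArray <- function(dim, center, r, spacing = c(1, 1, 1)) {
  co <- as.matrix(expand.grid(seq_len(dim[1]), seq_len(dim[2]),
                              seq_len(dim[3])))
  array(rowSums(sweep(sweep(co, 2, center), 2, spacing, "*")^2) <= r^2, dim)
}

# tiny synthetic stack with brown (BrdU+) discs drawn at given
# (row, col, section) positions on a pale tissue background
drawNucleusStack <- function(dimHW, nSections, positions, radius = 3) {
  brown <- c(70, 45, 30) / 255
  base <- c(222, 180, 190) / 255
  lapply(seq_len(nSections), function(s) {
    img <- array(rep(base, each = prod(dimHW)), c(dimHW, 3))
    ps <- positions[positions[, 3] == s, , drop = FALSE]
    if (nrow(ps)) {
      m <- matrix(FALSE, dimHW[1], dimHW[2])
      for (j in seq_len(nrow(ps)))
        m <- BudQuant:::fillEllipse(m, ps[j, 1], ps[j, 2], radius, radius)
      for (k in 1:3) {
        ch <- img[, , k]; ch[m] <- brown[k]; img[, , k] <- ch
      }
    }
    img
  })
}
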