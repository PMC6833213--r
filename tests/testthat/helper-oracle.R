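# Shared test machinery: an independent brute-force maximiser of the entropy
# criterion (dense grid start + derivative-free local refinement; never
# touches the closed-form solve), a random small-instance generator for the
# offline identification problem, and a zero-maintenance model.

# Maximise S(alpha, k1) by 41x41 grid over a broad box followed by two
# rounds of Nelder-Mead polishing.
gridRefineOracle <- function(sFun, aRange = c(0.05, 5), kRange = c(-0.05, 0.1),
                             nGrid = 41) {
  aG <- seq(aRange[1], aRange[2], length.out = nGrid)
  kG <- seq(kRange[1], kRange[2], length.out = nGrid)
  sM <- outer(aG, kG, Vectorize(sFun))
  ij <- which(sM == max(sM), arr.ind = TRUE)[1, ]
  opt <- optim(c(aG[ij[1]], kG[ij[2]]), function(p) -sFun(p[1], p[2]),
               method = "Nelder-Mead",
               control = list(reltol = 1e-15, maxit = 20000))
  opt <- optim(opt$par, function(p) -sFun(p[1], p[2]),
               method = "Nelder-Mead",
               control = list(reltol = 1e-15, maxit = 20000))
  c(alpha = opt$par[1], k1 = opt$par[2])
}

# One random small offline-identification instance: 5-12 samples of an
# increasing biomass trajectory, cOUR generated by the discrete two-phase
# balance with mild multiplicative noise.
randomStageAInstance <- function() {
  n <- sample(5:12, 1)
  tt <- sort(runif(n, 0.5, 20))
  x0 <- runif(1, 0.1, 0.5)
  x <- x0 * exp(cumsum(runif(n, 0.1, 0.4)))
  tI <- tt[sample(2:(n - 2), 1)]
  alphaTrue <- runif(1, 0.5, 2)
  k1True <- runif(1, 1e-3, 0.02)
  r <- coursense:::maintenanceRegressor(tt, x, tI)
  cour <- (alphaTrue * (x - x0) + k1True * r) * (1 + 0.03 * rnorm(n))
  list(dataset = offlineDataset(tt, x, x0), cour = cour, tI = tI,
       kExp = runif(1), alphaTrue = alphaTrue, k1True = k1True)
}

relDiff <- function(a, b) abs(a - b) / pmax(abs(b), 1e-8)

zeroMaintenance <- function() maintenanceModel(0, 0, 0, xSpecific = Inf, degree = 1)
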