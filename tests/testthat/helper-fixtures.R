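# programmatic fixtures shared across test files

random_dataset <- function(seed) {
  set.seed(seed)
  nr <- sample(1:12, 1)
  nc <- sample(1:5, 1)
  data <- matrix(round(rnorm(nr * nc) * 10^sample(-3:3, 1), 12), nr, nc)
  attrs <- list()
  for (k in seq_len(sample(0:4, 1))) {
    nm <- paste0("attr", k)
    attrs[[nm]] <- switch(sample(3, 1),
      rnorm(1),
      rnorm(sample(2:5, 1)),
      paste(sample(letters, 3), collapse = " "))
  }
  comments <- if (runif(1) < 0.5)
    replicate(sample(1:3, 1), paste(sample(letters, 5), collapse = ""))
  else character()
  roles <- c(X = 1L, Y = min(2L, nc))
  if (nc >= 3) roles <- c(roles, eY = 3L)
  dataSet(data, attributes = attrs, comments = comments, roles = roles)
}

# collection of exponential decays exp(-q^2 D t) at several q, gaussian noise
decay_collection <- function(qs = c(0.5, 1), D = 0.1, noise = 0.01,
                             seed = 42, t = seq(0, 30, 0.5)) {
  set.seed(seed)
  dataCollection(lapply(qs, function(qv) {
    y0 <- exp(-qv^2 * D * t)
    ey <- pmax(noise * y0, 1e-6)
    dataSet(cbind(t, y0 + rnorm(length(t), 0, ey), ey),
            attributes = list(q = qv))
  }))
}

expect_close <- function(x, y, tol) expect_lt(max(abs(x - y)), tol)

# first positive root of tan x = x (sphere intensity zero), by bisection
.sphere_zero_oracle <- function() {
  f <- function(x) sin(x) - x * cos(x)
  lo <- pi; hi <- 3 * pi / 2
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}
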