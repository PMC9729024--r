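# Independent brute-force oracles: direct transcriptions of the defining
# formulas, kept deliberately naive (explicit loops, no shared code with
# the package internals).

oracle_ewm <- function(x, span) {
  alpha <- 2 / (span + 1)
  n <- length(x)
  m <- s <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    j <- seq_len(i)
    w <- (1 - alpha)^(i - j)
    ok <- !is.na(x[j])
    if (!any(ok)) next
    w <- w[ok]; xv <- x[j][ok]
    mu <- sum(w * xv) / sum(w)
    m[i] <- mu
    denom <- 1 - sum(w^2) / sum(w)^2
    if (denom > 0)
      s[i] <- sqrt(max(0, sum(w * (xv - mu)^2) / sum(w)) / denom)
  }
  list(mean = m, sd = s)
}

oracle_spb1 <- function(task) {
  n <- task$n_frames
  total <- 0
  for (k in c("elbow", "wrist", "knee", "ankle")) {
    acc <- 0
    for (i in 2:n) {
      p <- task[[k]]
      acc <- acc + sqrt((p[i, 1] - p[i - 1, 1])^2 +
                          (p[i, 2] - p[i - 1, 2])^2) / task$trunk_length
    }
    total <- total + acc / (n - 1)
  }
  unname(total / 4)
}

oracle_spb2 <- function(task) {
  n <- task$n_frames
  best <- -Inf
  for (i in 2:n) {
    D <- 0
    for (k in c("elbow", "wrist", "knee", "ankle")) {
      p <- task[[k]]
      D <- D + sqrt((p[i, 1] - p[i - 1, 1])^2 +
                      (p[i, 2] - p[i - 1, 2])^2) / task$trunk_length
    }
    if (D > best) best <- D
  }
  unname(best)
}

cross3 <- function(o, a, b) (a[1] - o[1]) * (b[2] - o[2]) -
  (a[2] - o[2]) * (b[1] - o[1])

# Gift-wrapping hull + fan triangulation (independent of chull/shoelace)
oracle_hull_area <- function(pts) {
  pts <- unique(pts[stats::complete.cases(pts), , drop = FALSE])
  n <- nrow(pts)
  if (n < 3) return(0)
  ord <- order(pts[, 1], pts[, 2])
  start <- ord[1]
  hull <- integer(0)
  cur <- start
  repeat {
    hull <- c(hull, cur)
    nxt <- if (cur == 1L) 2L else 1L
    for (j in seq_len(n)) {
      if (j == cur || j == nxt) next
      cr <- cross3(pts[cur, ], pts[nxt, ], pts[j, ])
      d_j <- sum((pts[j, ] - pts[cur, ])^2)
      d_n <- sum((pts[nxt, ] - pts[cur, ])^2)
      if (cr > 0 || (cr == 0 && d_j > d_n)) nxt <- j
    }
    cur <- nxt
    if (cur == start) break
    if (length(hull) > n) stop("gift wrapping failed to close")
  }
  if (length(hull) < 3) return(0)
  area <- 0
  for (i in 2:(length(hull) - 1))
    area <- area + cross3(pts[hull[1], ], pts[hull[i], ], pts[hull[i + 1], ])
  unname(abs(area) / 2)
}

oracle_spb3 <- function(task) {
  total <- 0
  for (k in c("elbow", "wrist", "knee", "ankle"))
    total <- total + oracle_hull_area(task[[k]]) / task$trunk_length^2
  unname(total / task$n_frames)
}

# atan2-based unsigned angle in [0, 180] (independent of the acos route)
oracle_angle <- function(u, v) {
  unname(atan2(abs(u[1] * v[2] - u[2] * v[1]),
               u[1] * v[1] + u[2] * v[2]) * 180 / pi)
}

oracle_ag1 <- function(task) {
  n <- task$n_frames
  vals <- rep(NA_real_, n)
  overall <- sign(mean(task$shoulder[, 1] - task$hip[, 1]))
  for (i in seq_len(n)) {
    s <- sign(task$shoulder[i, 1] - task$hip[i, 1])
    if (s == 0) s <- overall
    m1 <- (task$elbow[i, ] + task$wrist[i, ]) / 2 - task$shoulder[i, ]
    m2 <- (task$knee[i, ] + task$ankle[i, ]) / 2 - task$hip[i, ]
    if (all(m1 == 0) || all(m2 == 0)) next
    vals[i] <- oracle_angle(c(s, 0), m1) + oracle_angle(c(-s, 0), m2)
  }
  unname(mean(vals, na.rm = TRUE))
}

oracle_phi <- function(task, i) {
  sh <- task$shoulder[i, ]; hp <- task$hip[i, ]
  el <- task$elbow[i, ]; wr <- task$wrist[i, ]
  kn <- task$knee[i, ]; an <- task$ankle[i, ]
  p1 <- oracle_angle(sh - hp, el - sh)
  if (el[2] < sh[2]) p1 <- 0
  p2 <- oracle_angle(hp - sh, kn - hp)
  if (kn[2] < hp[2]) p2 <- 0
  p3 <- oracle_angle(el - sh, wr - el)
  p4 <- oracle_angle(kn - hp, an - kn)
  c(p1, p2, p3, p4)
}

oracle_ag23 <- function(task) {
  Phi <- vapply(seq_len(task$n_frames),
                function(i) sum(oracle_phi(task, i)), numeric(1))
  c(ag2 = mean(Phi, na.rm = TRUE), ag3 = max(Phi, na.rm = TRUE))
}

# OLS + AIC from the normal equations and the Gaussian log-likelihood,
# written without lm()/AIC()
oracle_ols_aic <- function(X, y) {
  X1 <- cbind(1, as.matrix(X))
  beta <- solve(t(X1) %*% X1, t(X1) %*% y)
  rss <- sum((y - X1 %*% beta)^2)
  n <- length(y)
  k <- ncol(X1) + 1  # coefficients + sigma^2
  list(beta = as.numeric(beta),
       aic = n * log(2 * pi * rss / n) + n + 2 * k)
}

oracle_backward_aic <- function(data, response, candidates) {
  aic_of <- function(preds) {
    X <- if (length(preds)) data[, preds, drop = FALSE] else
      matrix(nrow = length(data[[response]]), ncol = 0)
    oracle_ols_aic(X, data[[response]])$aic
  }
  current <- sort(candidates)
  cur_aic <- aic_of(current)
  path <- character(0)
  while (length(current)) {
    aics <- vapply(current, function(p) aic_of(setdiff(current, p)),
                   numeric(1))
    b <- which.min(aics)
    if (aics[b] >= cur_aic) break
    path <- c(path, current[b])
    current <- setdiff(current, current[b])
    cur_aic <- unname(aics[b])
  }
  list(retained = current, aic = cur_aic, removed = path)
}
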