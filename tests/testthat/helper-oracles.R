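# Independent brute-force reference implementations (literal double loops),
# kept deliberately naive so they share nothing with the production code.

naiveBrenner <- function(img) {
  h <- nrow(img); w <- ncol(img); s <- 0
  for (y in 1:h) for (x in 1:(w - 2)) s <- s + (img[y, x + 2] - img[y, x])^2
  s
}

naiveTenengrad <- function(img) {
  h <- nrow(img); w <- ncol(img); s <- 0
  for (y in 2:(h - 1)) for (x in 2:(w - 1)) {
    sx <- (img[y - 1, x + 1] + 2 * img[y, x + 1] + img[y + 1, x + 1]) -
          (img[y - 1, x - 1] + 2 * img[y, x - 1] + img[y + 1, x - 1])
    sy <- (img[y + 1, x - 1] + 2 * img[y + 1, x] + img[y + 1, x + 1]) -
          (img[y - 1, x - 1] + 2 * img[y - 1, x] + img[y - 1, x + 1])
    s <- s + sx^2 + sy^2
  }
  s
}

naiveNormVar <- function(img) {
  mu <- mean(img)
  s <- 0
  for (y in 1:nrow(img)) for (x in 1:ncol(img)) s <- s + (img[y, x] - mu)^2
  s / mu
}

# Exhaustive template scan with the sequential compare-and-record rule.
naiveLocate <- function(img, tpl, measure) {
  m <- nrow(tpl@patch); n <- ncol(tpl@patch)
  best <- -Inf; bestIJ <- c(NA, NA)
  for (i in 0:(nrow(img) - m)) for (j in 0:(ncol(img) - n)) {
    f <- img[(i + 1):(i + m), (j + 1):(j + n)]
    s <- if (measure == "eq9_unnormalized") sum(tpl@patch * f) else {
      d <- sqrt(sum(f * f)); if (d == 0) 0 else sum(tpl@patch * f) / d
    }
    if (s > best) { best <- s; bestIJ <- c(i, j) }
  }
  list(origin = bestIJ, score = best)
}

# Exhaustive Otsu: try every cut, score between-class variance directly.
bruteOtsu <- function(img) {
  v <- as.vector(round(img))
  best <- -Inf; bestT <- NA
  for (t0 in 0:254) {
    lo <- v[v <= t0]; hi <- v[v > t0]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(v); w1 <- 1 - w0
    sb <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (sb > best) { best <- sb; bestT <- t0 }
  }
  bestT
}

cropTemplate <- function(img, i, j, m, n, L = 3, H = 2) {
  TipTemplate(img[(i + 1):(i + m), (j + 1):(j + n)], offsetL = L, offsetH = H)
}
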