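# Gaussian-copula information metrics and graph measures.

test_that("copula transform produces standard-normal margins", {
  with_seed_test(31, {
    x <- matrix(rexp(3000), nrow = 3)
    z <- copula_transform(x)
    expect_equal(unname(rowMeans(z)), rep(0, 3), tolerance = 0.01)
    expect_equal(unname(apply(z, 1, var)), rep(1, 3), tolerance = 0.01)
    ks <- stats::ks.test(z[1, ], "pnorm")
    expect_gt(ks$p.value, 0.01)
  })
})

test_that("copula transform is invariant to monotone maps and flags ties", {
  with_seed_test(32, {
    x <- rnorm(500)
    z1 <- copula_transform(rbind(x, x * 2))
    z2 <- copula_transform(rbind(exp(x), x * 2))
    expect_equal(z1[1, ], z2[1, ], tolerance = 1e-12)
    tied <- c(rep(1:20, each = 30), rnorm(0))
    zt <- copula_transform(rbind(tied, rnorm(600)))
    expect_identical(attr(zt, "ties_flagged"), 1L)
    expect_error(copula_transform(rbind(rep(1:4, 25), rnorm(100))),
                 "distinct")
  })
})

test_that("copula MI approaches the Gaussian closed form", {
  with_seed_test(33, {
    for (rho in c(0, 0.3, 0.6, 0.9)) {
      n <- 4096
      x <- rnorm(n)
      y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
      w <- mi_matrix(copula_transform(rbind(x, y)))
      expect_lt(abs(w[1, 2] - (-0.5 * log(1 - rho^2))), 0.02)
    }
  })
})

test_that("MI caps duplicated rows and vanishes under independence", {
  with_seed_test(34, {
    x <- rnorm(4096)
    w <- mi_matrix(copula_transform(rbind(x, x + 0, rnorm(4096))))
    expect_true(attr(w, "capped"))
    expect_equal(w[1, 2], -0.5 * log(1e-12))
    expect_lt(w[1, 3], 0.01)
    expect_true(all(w >= 0) && all(diag(w) == 0))
    expect_equal(w, t(w))
  })
})

test_that("CMI vanishes on a Gaussian chain and for independent ROIs", {
  with_seed_test(35, {
    n <- 8192
    x <- rnorm(n)
    y <- 0.8 * x + 0.6 * rnorm(n)
    z <- 0.8 * y + 0.6 * rnorm(n)
    w <- cmi_matrix(copula_transform(rbind(x, y, z)))
    expect_lt(w[1, 3], 0.01)
    expect_gt(w[1, 2], 0.1)
    ind <- cmi_matrix(copula_transform(matrix(rnorm(4 * n), 4)))
    expect_lt(max(ind[upper.tri(ind)]), 0.01)
  })
})

test_that("CMI equals MI for two ROIs", {
  with_seed_test(36, {
    z <- copula_transform(matrix(rnorm(2 * 1024), 2))
    expect_equal(cmi_matrix(z), mi_matrix(z))
  })
})

test_that("O-information separates independence, redundancy, and matches the
          analytic log-determinant form", {
  with_seed_test(37, {
    n <- 8192
    zi <- copula_transform(matrix(rnorm(3 * n), 3))
    expect_lt(abs(o_information(zi)$omega), 0.01)
    lat <- rnorm(n)
    reds <- t(vapply(1:3, function(i) 0.9 * lat + sqrt(1 - 0.81) * rnorm(n),
                     numeric(n)))
    expect_gt(o_information(copula_transform(reds))$omega, 0)
    expect_error(o_information(zi, subset = 1:2), "spec error")
  })
  # closed-form oracle on an analytic trivariate correlation matrix
  r <- matrix(c(1, .5, .3, .5, 1, .2, .3, .2, 1), 3)
  h <- function(m) 0.5 * (nrow(m) * log(2 * pi * exp(1)) +
                            as.numeric(determinant(m)$modulus))
  oracle <- 1 * h(r) +
    sum(vapply(1:3, function(i) h(r[i, i, drop = FALSE]) -
                 h(r[-i, -i, drop = FALSE]), numeric(1)))
  expect_equal(neurodyn:::o_info_from_cor(r), oracle, tolerance = 1e-9)
})

test_that("graph metrics are exact on canonical small graphs", {
  w3 <- matrix(1, 3, 3) - diag(3)
  gm <- graph_metrics(w3)
  expect_equal(gm$global_efficiency, 1)
  expect_equal(gm$transitivity, 1)
  expect_equal(gm$density, 1)
  path <- matrix(0, 3, 3)
  path[1, 2] <- path[2, 1] <- path[2, 3] <- path[3, 2] <- 1
  expect_equal(graph_metrics(path)$global_efficiency, (1 + 1 + 0.5) / 3)
  expect_error(graph_metrics(matrix(0, 3, 3)), "degenerate")
  expect_error(graph_metrics(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("Dijkstra efficiency equals brute-force enumeration on small graphs", {
  brute_geff <- function(w) {
    n <- nrow(w)
    len <- ifelse(w > 0, 1 / w, Inf)
    d <- matrix(Inf, n, n)
    diag(d) <- 0
    perms <- function(v) if (length(v) <= 1) list(v) else
      do.call(c, lapply(seq_along(v), function(i)
        lapply(perms(v[-i]), function(p) c(v[i], p))))
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      mids <- setdiff(1:n, c(i, j))
      best <- len[i, j]
      for (k in seq_along(mids)) {
        for (sub in utils::combn(mids, k, simplify = FALSE)) {
          for (ord in perms(sub)) {
            pth <- c(i, ord, j)
            best <- min(best, sum(len[cbind(pth[-length(pth)], pth[-1])]))
          }
        }
      }
      d[i, j] <- d[j, i] <- best
    }
    mean(1 / d[upper.tri(d)])
  }
  with_seed_test(38, {
    for (n in c(4, 5, 6)) {
      w <- matrix(0, n, n)
      w[upper.tri(w)] <- runif(n * (n - 1) / 2) * rbinom(n * (n - 1) / 2, 1, 0.7)
      w <- w + t(w)
      if (max(w) == 0) next
      w <- w / max(w)
      expect_equal(graph_metrics(w)$global_efficiency, brute_geff(w),
                   tolerance = 1e-10)
    }
  })
})

test_that("small-worldness exceeds 1 on a rewired ring lattice, near 1 on
          dense random graphs", {
  with_seed_test(39, {
    n <- 30
    a <- matrix(0, n, n)
    for (i in 1:n) for (d in 1:3) {
      j <- ((i + d - 1) %% n) + 1
      a[i, j] <- a[j, i] <- 1
    }
    # rewire ~10% of edges
    edges <- which(a == 1 & upper.tri(a), arr.ind = TRUE)
    for (e in sample(nrow(edges), round(0.1 * nrow(edges)))) {
      i <- edges[e, 1]
      cand <- setdiff(which(a[i, ] == 0), i)
      if (length(cand)) {
        j_new <- sample(cand, 1)
        a[edges[e, 1], edges[e, 2]] <- a[edges[e, 2], edges[e, 1]] <- 0
        a[i, j_new] <- a[j_new, i] <- 1
      }
    }
    ws <- a * matrix(runif(n * n, 0.8, 1), n, n)
    ws <- (ws + t(ws)) / 2
    sigma_sw <- graph_metrics(ws, sw_density = 0.18, seed = 5)$small_worldness
    expect_gt(sigma_sw, 1)
    er <- matrix(0, n, n)
    er[upper.tri(er)] <- rbinom(n * (n - 1) / 2, 1, 0.5) * runif(n * (n - 1) / 2, .5, 1)
    er <- er + t(er)
    sigma_er <- graph_metrics(er, sw_density = 0.5, seed = 5)$small_worldness
    expect_lt(abs(sigma_er - 1), 0.3)
  })
})

test_that("connectivity outputs are equivariant under ROI relabeling", {
  rec <- noise_recording(fs = 128, duration = 30, n_ch = 5, seed = 40,
                         common = 0.3)
  perm <- c(4, 2, 5, 1, 3)
  rec_p <- recording(rec$data[perm, ], fs = rec$fs, labels = rec$labels[perm])
  g1 <- connectivity_graph(rec)
  g2 <- connectivity_graph(rec_p)
  expect_equal(g2$w_mi, g1$w_mi[perm, perm], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(g2$w_cmi, g1$w_cmi[perm, perm], tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(g2$omega, g1$omega, tolerance = 1e-12)
  expect_equal(g2$w_oinfo, g1$w_oinfo[perm, perm], tolerance = 1e-10,
               ignore_attr = TRUE)
})
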