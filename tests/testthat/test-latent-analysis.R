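test_that("embeddings obey the linear shift identity and ignore cell order", {
  d <- tiny_dataset()
  lab <- fit_labels(control_cells(d), k = 4)
  cfg <- model_config(n = 4, hidden = 16, shift_hidden = 8, epochs = 2,
                      batch_size = 32, seed = 1)
  m <- fit_scm_vae(d, lab, NULL, cfg)
  Xc <- control_cells(d)
  emb <- embed_perturbations(m, Xc, perturbations = c("G001", "G002"), seed = 1)
  M <- solve(diag(4) - m$par$A_free * m$mask$mask)
  e <- perturbscm:::embedding_matrix(emb)
  # control row equals the mean propagated posterior mean
  post <- encode_expression(m, Xc)
  expect_equal(unname(e["non-targeting", ]), unname(drop(M %*% colMeans(post$mean))))
  # mean U^p - mean U^0 = c (I - A)^-1 S exactly
  for (p in c("G001", "G002")) {
    sc <- perturbscm:::shift_for(m, p)
    expect_equal(unname(e[p, ] - e["non-targeting", ]),
                 unname(drop(M %*% (sc$c * sc$S))), tolerance = 1e-10)
  }
  # invariance to control-cell ordering (posterior mean path has no sampling)
  emb2 <- embed_perturbations(m, Xc[rev(seq_len(nrow(Xc))), ],
                              perturbations = c("G001", "G002"), seed = 1)
  expect_equal(perturbscm:::embedding_matrix(emb2), e, tolerance = 1e-10)
})

test_that("distance concordance reports pairs and handles degeneracy", {
  d <- tiny_dataset()
  lab <- fit_labels(control_cells(d), k = 4)
  cfg <- model_config(n = 4, hidden = 16, shift_hidden = 8, epochs = 2,
                      batch_size = 32, seed = 2)
  m <- fit_scm_vae(d, lab, NULL, cfg)
  emb <- embed_perturbations(m, control_cells(d),
                             perturbations = c("G001", "G002"), seed = 1)
  cc <- suppressMessages(distance_concordance(emb, d))
  expect_equal(nrow(cc$pairs), 2)
  expect_true(all(cc$pairs$mmd >= 0))
  # an untrained model has all-zero shifts: degenerate correlation is NA
  m0 <- toy_model(d)
  m0$c_pen <- c(G001 = 1, G002 = 1)
  emb0 <- embed_perturbations(m0, control_cells(d),
                              perturbations = c("G001", "G002"), seed = 1)
  cc0 <- suppressMessages(distance_concordance(emb0, d))
  expect_true(is.na(cc0$correlation))
})

test_that("penetrance sweeps are deterministic and anchored at control near c = 0", {
  d <- tiny_dataset(n_ctrl = 150, n_pert = 80)
  lab <- fit_labels(control_cells(d), k = 4)
  cfg <- model_config(n = 4, hidden = 16, shift_hidden = 8, epochs = 10,
                      batch_size = 64, seed = 3)
  m <- fit_scm_vae(d, lab, NULL, cfg)
  sw <- penetrance_sweep(m, "G001", control_cells(d), c_values = c(-1, 0, 1, 2),
                         B = 40, seed = 5)
  sw2 <- penetrance_sweep(m, "G001", control_cells(d), c_values = c(-1, 0, 1, 2),
                          B = 40, seed = 5)
  expect_equal(sw$mmd_to_control, sw2$mmd_to_control, tolerance = 1e-12)
  # the zero-shift output stays nearer control than a strong intervention
  expect_lt(sw$mmd_to_control[sw$c == 0], sw$mmd_to_control[sw$c == 2])
})
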