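# Modelling-technique adapters for the SDM ensemble.
#
# Each adapter is a list(label, fit(x, y, seed), predict(fit, x)) mapping a
# predictor data.frame and a 0/1 response to a fitted object and back to
# probabilities in [0, 1]. The families follow the classic ensemble
# platform's roster: three regression methods (GLM, GAM, MARS-style adaptive
# splines), two classification methods (CTA, MDA) and three machine-learning
# methods (ANN, GBM, RF), with the stated tuning conventions (quadratic terms
# plus stepwise AIC for GLM, ~3 effective df smooths for GAM, at most 2,000
# trees for the boosted model, five-fold cross-validation for the neural
# network).

#' Available SDM technique identifiers
#'
#' @return character vector of the eight built-in technique names.
#' @export
sdm_techniques <- function() {
  c("GLM", "GAM", "MARS", "CTA", "MDA", "ANN", "GBM", "RF")
}

technique_adapter <- function(name) {
  switch(name,
    GLM = adapter_glm(), GAM = adapter_gam(), MARS = adapter_mars(),
    CTA = adapter_cta(), MDA = adapter_mda(), ANN = adapter_ann(),
    GBM = adapter_gbm(), RF = adapter_rf(),
    stop_config("unknown modelling technique '%s' (available: %s)",
                name, paste(sdm_techniques(), collapse = ", "))
  )
}

clamp01 <- function(p) pmin(pmax(as.numeric(p), 0), 1)

# Generalized linear model with quadratic terms, stepwise selection by AIC.
adapter_glm <- function() {
  list(
    label = "GLM (quadratic, stepwise AIC)",
    fit = function(x, y, seed) {
      d <- cbind(.y = y, x)
      terms_lin <- colnames(x)
      terms_quad <- sprintf("I(%s^2)", colnames(x))
      full <- stats::as.formula(
        paste(".y ~", paste(c(terms_lin, terms_quad), collapse = " + ")))
      m0 <- suppressWarnings(glm(full, family = binomial(), data = d))
      suppressWarnings(step(m0, direction = "both", trace = 0))
    },
    predict = function(fit, x) clamp01(predict(fit, newdata = x,
                                               type = "response"))
  )
}

# Generalized additive model; thin-plate smooths with basis dimension 4
# (about three effective degrees of freedom per term).
adapter_gam <- function() {
  list(
    label = "GAM (smooth terms, ~3 df)",
    fit = function(x, y, seed) {
      d <- cbind(.y = y, x)
      tms <- vapply(colnames(x), function(v) {
        if (length(unique(x[[v]])) >= 8) sprintf("s(%s, k = 4)", v) else v
      }, character(1))
      f <- stats::as.formula(paste(".y ~", paste(tms, collapse = " + ")))
      mgcv::gam(f, family = binomial(), data = d)
    },
    predict = function(fit, x) clamp01(predict(fit, newdata = x,
                                               type = "response"))
  )
}

# Adaptive piecewise-linear (hinge) regression: MARS-style basis of hinge
# pairs at interior quantile knots, fitted by lasso-penalized logistic
# regression so the basis is selected adaptively.
mars_basis <- function(x, knots = NULL) {
  cols <- list(); nm <- character(0)
  if (is.null(knots)) {
    knots <- lapply(x, function(v) {
      if (length(unique(v)) < 5) return(numeric(0))
      unique(quantile(v, c(0.25, 0.5, 0.75), names = FALSE))
    })
    names(knots) <- colnames(x)
  }
  for (v in colnames(x)) {
    cols[[length(cols) + 1L]] <- x[[v]]; nm <- c(nm, v)
    for (k in knots[[v]]) {
      cols[[length(cols) + 1L]] <- pmax(x[[v]] - k, 0)
      cols[[length(cols) + 1L]] <- pmax(k - x[[v]], 0)
      nm <- c(nm, sprintf("%s_h%+.4g", v, k), sprintf("%s_l%+.4g", v, k))
    }
  }
  m <- do.call(cbind, cols); colnames(m) <- nm
  list(basis = m, knots = knots)
}

adapter_mars <- function() {
  list(
    label = "MARS-style hinge regression (lasso-selected)",
    fit = function(x, y, seed) {
      b <- mars_basis(x)
      cv <- with_seed(seed, glmnet::cv.glmnet(b$basis, y, family = "binomial",
                                              nfolds = 5))
      list(cv = cv, knots = b$knots)
    },
    predict = function(fit, x) {
      b <- mars_basis(x, knots = fit$knots)
      clamp01(predict(fit$cv, newx = b$basis, s = "lambda.min",
                      type = "response"))
    }
  )
}

# Classification tree analysis.
adapter_cta <- function() {
  list(
    label = "CTA (classification tree)",
    fit = function(x, y, seed) {
      d <- cbind(.y = factor(y, levels = c(0, 1)), x)
      with_seed(seed, rpart::rpart(.y ~ ., data = d, method = "class",
                                   control = rpart::rpart.control(cp = 0.005,
                                                                  xval = 5)))
    },
    predict = function(fit, x) clamp01(predict(fit, newdata = x)[, "1"])
  )
}

# Mixture discriminant analysis (Gaussian mixture per class).
adapter_mda <- function() {
  list(
    label = "MDA (Gaussian mixture discriminant analysis)",
    fit = function(x, y, seed) {
      # MclustDA resolves these helpers in its caller's frame; make them
      # visible without attaching mclust
      mclustBIC <- mclust::mclustBIC
      mclustModelNames <- mclust::mclustModelNames
      with_seed(seed,
        mclust::MclustDA(x, factor(y, levels = c(0, 1)), G = 1:2,
                         modelNames = c("EII", "EEE", "VVV"),
                         verbose = FALSE))
    },
    predict = function(fit, x) clamp01(predict(fit, newdata = x)$z[, "1"])
  )
}

# Feed-forward neural network; weight decay chosen by five-fold
# cross-validation, inputs standardized.
adapter_ann <- function() {
  list(
    label = "ANN (single hidden layer, 5-fold CV decay)",
    fit = function(x, y, seed) {
      ctr <- vapply(x, mean, 0); scl <- vapply(x, function(v) max(sd(v), 1e-9), 0)
      xs <- scale(as.matrix(x), center = ctr, scale = scl)
      decays <- c(0.001, 0.01, 0.1)
      with_seed(seed, {
        folds <- sample(rep_len(1:5, nrow(xs)))
        cv_auc <- vapply(decays, function(dc) {
          aucs <- vapply(1:5, function(f) {
            tr <- folds != f
            if (length(unique(y[tr])) < 2 || length(unique(y[!tr])) < 2)
              return(NA_real_)
            m <- nnet::nnet(xs[tr, , drop = FALSE], y[tr], size = 8,
                            decay = dc, maxit = 200, trace = FALSE)
            evaluate_roc(y[!tr], predict(m, xs[!tr, , drop = FALSE]))$auc
          }, 0)
          mean(aucs, na.rm = TRUE)
        }, 0)
        best <- decays[which.max(cv_auc)]
        m <- nnet::nnet(xs, y, size = 8, decay = best, maxit = 300,
                        trace = FALSE)
        list(net = m, center = ctr, scale = scl, decay = best)
      })
    },
    predict = function(fit, x) {
      xs <- scale(as.matrix(x), center = fit$center, scale = fit$scale)
      clamp01(predict(fit$net, xs))
    }
  )
}

# Gradient-boosted trees, at most 2,000 trees with early stopping on an
# inner holdout.
adapter_gbm <- function() {
  list(
    label = "GBM (gradient-boosted trees, <= 2000 trees)",
    fit = function(x, y, seed) {
      xm <- as.matrix(x)
      with_seed(seed, {
        n <- nrow(xm)
        hold <- sample.int(n, max(2L, floor(0.2 * n)))
        dtr <- xgboost::xgb.DMatrix(xm[-hold, , drop = FALSE],
                                    label = y[-hold])
        dva <- xgboost::xgb.DMatrix(xm[hold, , drop = FALSE],
                                    label = y[hold])
        xgboost::xgb.train(
          params = list(objective = "binary:logistic", eta = 0.05,
                        max_depth = 3, subsample = 0.8, nthread = 1),
          data = dtr, nrounds = 2000, evals = list(val = dva),
          early_stopping_rounds = 25, verbose = 0)
      })
    },
    predict = function(fit, x) clamp01(predict(fit, as.matrix(x)))
  )
}

# Random forest.
adapter_rf <- function() {
  list(
    label = "RF (random forest, 500 trees)",
    fit = function(x, y, seed) {
      with_seed(seed,
        randomForest::randomForest(x, factor(y, levels = c(0, 1)),
                                   ntree = 500))
    },
    predict = function(fit, x) clamp01(predict(fit, newdata = x,
                                               type = "prob")[, "1"])
  )
}
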