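{
  "logistic_regression": { "lambda": [0.0001, 0.001, 0.01, 0.1] },
  "svm": { "kernel": ["linear", "radial"], "cost": [0.1, 1, 10] },
  "decision_tree": { "maxdepth": [3, 5, 10, 20], "minsplit": [2, 10, 20] },
  "knn": { "k": [1, 3, 5, 11, 25], "metric": ["manhattan", "euclidean"] },
  "random_forest": { "ntree": [100, 200, 500], "mtry_frac": [0.05, 0.1, 0.3] },
  "extra_trees": { "num_trees": [100, 200, 500] },
  "adaboost": { "n_estimators": [25, 50, 100], "learning_rate": [0.1, 0.5, 1] },
  "gradient_boosting": { "nrounds": [50, 100, 200], "eta": [0.05, 0.1, 0.3], "max_depth": [2, 3, 5] },
  "bagging": { "n_estimators": [25, 50, 100] }
}
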