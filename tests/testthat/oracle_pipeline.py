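"""Naive re-implementation of the electrode-classification chain.

Independent oracle: dual-QP linear SVM via scipy SLSQP, explicit
leave-one-out loops, explicit enumeration of class-size-preserving
labelings. Reads {"X": raw feature matrix, "y": labels, "grid": C grid}
as JSON argv[1]; prints {"selected_C", "cv_by_c", "loo", "p", "dist"}.
"""
import sys, json, itertools
import numpy as np
from scipy.optimize import minimize

def svm_dual(X, y, C):
    n = len(y)
    Q = (y[:, None] * y[None, :]) * (X @ X.T)
    fun = lambda a: -(a.sum() - 0.5 * a @ Q @ a)
    jac = lambda a: -(np.ones(n) - Q @ a)
    cons = [{"type": "eq", "fun": lambda a: a @ y, "jac": lambda a: y}]
    a0 = np.full(n, min(C, 1.0) / 2)
    r = minimize(fun, a0, jac=jac, bounds=[(0, C)] * n, constraints=cons,
                 method="SLSQP", options={"maxiter": 5000, "ftol": 1e-14})
    a = r.x
    w = (a * y) @ X
    free = (a > 1e-7 * C) & (a < C * (1 - 1e-7))
    if free.any():
        return w, float(np.mean(y[free] - X[free] @ w))
    g = X @ w
    at_C = a >= C * (1 - 1e-7)
    ub, lb = [], []
    for i in range(n):
        if y[i] > 0:
            (ub if at_C[i] else lb).append(1 - g[i])
        else:
            (lb if at_C[i] else ub).append(-1 - g[i])
    if lb and ub:
        return w, (max(lb) + min(ub)) / 2
    return w, (min(ub) if ub else max(lb))

def loo(X, y, C):
    n = len(y)
    ok = 0
    for i in range(n):
        m = np.ones(n, bool); m[i] = False
        labs = sorted(set(y[m]))
        if len(labs) == 1:
            ok += (y[i] == labs[0]); continue
        ynum = np.where(y[m] == labs[0], 1.0, -1.0)
        w, b = svm_dual(X[m], ynum, C)
        d = X[i] @ w + b
        pred = labs[0] if d >= 0 else labs[1]
        ok += (pred == y[i])
    return ok / n

def main():
    data = json.load(open(sys.argv[1]))
    X = np.array(data["X"], float)
    y = np.array(data["y"])
    grid = sorted(data["grid"])
    # population-sd z-scoring per feature
    X = (X - X.mean(0)) / X.std(0)
    cv = [loo(X, y, C) for C in grid]
    C_sel = grid[int(np.argmax(cv))]          # ties -> smallest (first)
    obs = loo(X, y, C_sel)
    labs = sorted(set(y))
    n1 = int((y == labs[0]).sum())
    dist = []
    for pos in itertools.combinations(range(len(y)), n1):
        yp = np.array([labs[0] if i in pos else labs[1] for i in range(len(y))])
        dist.append(loo(X, yp, C_sel))
    dist = np.array(dist)
    p = float((dist >= obs - 1e-12).mean())
    print(json.dumps({"selected_C": C_sel, "cv_by_c": cv, "loo": obs,
                      "p": p, "dist": dist.tolist()}))

main()
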