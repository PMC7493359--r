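"""Reference solver for the weighted sparse-group lasso objective.

Reads a JSON array of problem instances, minimizes

    (1/2n) ||y - X b - Z u||^2
      + alpha * lam * sum_j wf_j |u_j|
      + (1 - alpha) * lam * sum_l wg_l ||u_(l)||_2

for each with SciPy's SLSQP on a smooth epigraph reformulation
(auxiliary a_j >= |u_j| and s_l >= ||u_(l)||, the group norm smoothed by a
delta = 1e-10 inside the square root, which perturbs the optimum by at most
wg_l * lam * delta), and writes a JSON array of objective values evaluated
on the exact non-smooth objective at the minimizer.

Usage: python sgl_reference.py problems.json results.json
"""
import json
import sys

import numpy as np
from scipy.optimize import minimize

DELTA = 1e-10


def solve_one(prob):
    y = np.asarray(prob["y"], dtype=float)
    Z = np.asarray(prob["Z"], dtype=float)
    if Z.ndim == 1:
        Z = Z.reshape(len(y), -1)
    X = prob.get("X")
    if X is None:
        X = np.zeros((len(y), 0))
    else:
        X = np.asarray(X, dtype=float)
        if X.ndim == 1:
            X = X.reshape(len(y), -1)
    groups = np.atleast_1d(np.asarray(prob["groups"], dtype=int))  # 1-based
    wf = np.atleast_1d(np.asarray(prob["wf"], dtype=float))
    wg = np.atleast_1d(np.asarray(prob["wg"], dtype=float))
    lam = float(prob["lambda"])
    alpha = float(prob["alpha"])
    n, p = Z.shape
    q = X.shape[1]
    L = len(wg)
    members = [np.where(groups == l + 1)[0] for l in range(L)]

    def exact_obj(b, u):
        r = y - X @ b - Z @ u
        val = 0.5 * np.dot(r, r) / n
        val += alpha * lam * np.sum(wf * np.abs(u))
        for l in range(L):
            val += (1 - alpha) * lam * wg[l] * np.linalg.norm(u[members[l]])
        return val

    # variables: [b (q), u (p), a (p), s (L)]
    nb, nu, na = q, p, p

    def unpack(x):
        return x[:nb], x[nb:nb + nu], x[nb + nu:nb + nu + na], x[nb + nu + na:]

    def fun(x):
        b, u, a, s = unpack(x)
        r = y - X @ b - Z @ u
        return (0.5 * np.dot(r, r) / n
                + alpha * lam * np.sum(wf * a)
                + (1 - alpha) * lam * np.sum(wg * s))

    def grad(x):
        b, u, a, s = unpack(x)
        r = y - X @ b - Z @ u
        return np.concatenate([
            -X.T @ r / n, -Z.T @ r / n,
            alpha * lam * wf, (1 - alpha) * lam * wg])

    cons = []
    for j in range(p):
        for sgn in (1.0, -1.0):
            def c(x, j=j, sgn=sgn):
                return x[nb + nu + j] - sgn * x[nb + j]

            def cj(x, j=j, sgn=sgn):
                g = np.zeros_like(x)
                g[nb + nu + j] = 1.0
                g[nb + j] = -sgn
                return g
            cons.append({"type": "ineq", "fun": c, "jac": cj})
    for l in range(L):
        idx = members[l]

        def c(x, l=l, idx=idx):
            u = x[nb:nb + nu]
            return x[nb + nu + na + l] - np.sqrt(
                np.dot(u[idx], u[idx]) + DELTA * DELTA)

        def cj(x, l=l, idx=idx):
            u = x[nb:nb + nu]
            g = np.zeros_like(x)
            nrm = np.sqrt(np.dot(u[idx], u[idx]) + DELTA * DELTA)
            g[nb + idx] = -u[idx] / nrm
            g[nb + nu + na + l] = 1.0
            return g
        cons.append({"type": "ineq", "fun": c, "jac": cj})

    def pack(b, u):
        a = np.abs(u) + 1e-8
        s = np.array([np.sqrt(np.dot(u[m], u[m]) + DELTA * DELTA) + 1e-8
                      for m in members])
        return np.concatenate([b, u, a, s])

    starts = [pack(np.zeros(q), np.zeros(p))]
    # warm start from the ridge-regularized least-squares fit
    W = np.hstack([X, Z])
    if W.shape[1] > 0:
        beta = np.linalg.lstsq(
            np.vstack([W, 1e-6 * np.eye(W.shape[1])]),
            np.concatenate([y, np.zeros(W.shape[1])]), rcond=None)[0]
        starts.append(pack(beta[:q], beta[q:]))

    best_val = np.inf
    best_bu = (np.zeros(q), np.zeros(p))
    for x0 in starts:
        res = minimize(fun, x0, jac=grad, method="SLSQP", constraints=cons,
                       options={"maxiter": 2000, "ftol": 1e-14})
        b, u, _, _ = unpack(res.x)
        val = exact_obj(b, u)
        if val < best_val:
            best_val = val
            best_bu = (b, u)
    return {"objective": best_val,
            "b": list(best_bu[0]), "u": list(best_bu[1])}


def main():
    infile, outfile = sys.argv[1], sys.argv[2]
    with open(infile) as fh:
        problems = json.load(fh)
    results = [solve_one(p) for p in problems]
    with open(outfile, "w") as fh:
        json.dump(results, fh)


if __name__ == "__main__":
    main()
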