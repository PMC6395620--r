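"""Solve the precision/density LP relaxation with HiGHS (scipy.optimize.linprog).

Called by the R package with two arguments: an input JSON file and an output
JSON path.  Input fields:
  n            number of nodes
  p            n x n matrix of pair-order probabilities (reciprocal)
  eps          list of density floors to solve
  transitivity "cutting" (default) or "full"
  tol          violation tolerance for cutting planes
  max_cuts     cuts added per separation round
  want_x       include the optimizing fractional x per epsilon

The fractional objective sum(p_uv x_uv) / sum(x_uv) over ordered pairs with
antisymmetry, transitivity and minimum-density constraints is linearized by
the Charnes-Cooper substitution y = t*x with sum(y) = 1; the antisymmetry
rows imply y <= t (hence x <= 1).  Transitivity rows are independent of the
density floor, so the cut pool is shared across the epsilon grid.
"""
import json
import sys

import numpy as np
import scipy.sparse as sp
from scipy.optimize import linprog


def main(inp_path, out_path):
    with open(inp_path) as fh:
        cfg = json.load(fh)
    n = int(cfg["n"])
    p = np.asarray(cfg["p"], dtype=float).reshape(n, n)
    eps_list = [float(e) for e in cfg["eps"]]
    mode = cfg.get("transitivity", "cutting")
    tol = float(cfg.get("tol", 1e-6))
    max_rounds = int(cfg.get("max_rounds", 40))
    max_cuts = int(cfg.get("max_cuts", 4000))
    want_x = bool(cfg.get("want_x", False))

    npairs = n * (n - 1) / 2.0
    nv = n * n + 1
    t_col = n * n

    def vid(u, v):
        return u * n + v

    c = np.zeros(nv)
    c[: n * n] = -p.flatten()
    bounds = [(0.0, 0.0) if u == v else (0.0, None)
              for u in range(n) for v in range(n)]
    bounds.append((0.0, 4.0 * max(npairs, 1.0)))  # cap on t; harmless, see docs

    rows, cols, vals, b_ub = [], [], [], []
    r = 0
    for u in range(n):
        for v in range(u + 1, n):
            rows += [r, r, r]
            cols += [vid(u, v), vid(v, u), t_col]
            vals += [1.0, 1.0, -1.0]
            b_ub.append(0.0)
            r += 1
    off = [vid(u, v) for u in range(n) for v in range(n) if u != v]
    A_eq = sp.coo_matrix((np.ones(len(off)), (np.zeros(len(off), int), off)),
                         shape=(1, nv))

    if mode == "full":
        for u in range(n):
            for v in range(n):
                if v == u:
                    continue
                for w in range(n):
                    if w == u or w == v:
                        continue
                    rows += [r] * 4
                    cols += [vid(u, v), vid(v, w), vid(u, w), t_col]
                    vals += [1.0, 1.0, -1.0, -1.0]
                    b_ub.append(0.0)
                    r += 1

    diag_mask = np.zeros((n, n, n), dtype=bool)
    for a in range(n):
        diag_mask[a, a, :] = True
        diag_mask[a, :, a] = True
        diag_mask[:, a, a] = True

    def solve_once(eps):
        nonlocal rows, cols, vals, b_ub, r
        # density row for this epsilon: -sum(y) + eps*npairs*t <= 0
        drow_cols = off + [t_col]
        drow_vals = [-1.0] * len(off) + [eps * npairs]
        rounds = 0
        prev_obj = None
        while True:
            A = sp.coo_matrix(
                (vals + drow_vals, (rows + [r] * len(drow_cols),
                                    cols + drow_cols)),
                shape=(r + 1, nv))
            res = linprog(c, A_ub=A, b_ub=b_ub + [0.0], A_eq=A_eq,
                          b_eq=[1.0], bounds=bounds, method="highs")
            if res.status != 0:
                return None, res.status, rounds
            rounds += 1
            if mode == "full":
                return res, 0, rounds
            if rounds >= max_rounds:
                # stopping with open cuts keeps a valid (looser) upper bound
                return res, 0, rounds
            if prev_obj is not None and prev_obj - (-res.fun) < 1e-9 and rounds >= 3:
                # the optimum has stalled; remaining violations are marginal
                return res, 0, rounds
            prev_obj = -res.fun
            y = res.x[: n * n].reshape(n, n)
            t = res.x[t_col]
            S = y[:, :, None] + y[None, :, :] - y[:, None, :] - t
            S[diag_mask] = -1.0
            viol = np.argwhere(S > tol)
            if viol.shape[0] == 0:
                return res, 0, rounds
            if viol.shape[0] > max_cuts:
                sc = S[S > tol]
                keep = np.argsort(-sc)[:max_cuts]
                viol = viol[keep]
            for (u, v, w) in viol:
                rows += [r] * 4
                cols += [vid(u, v), vid(v, w), vid(u, w), t_col]
                vals += [1.0, 1.0, -1.0, -1.0]
                b_ub.append(0.0)
                r += 1

    out = {"status": "ok", "bounds": [], "rounds": [], "t": []}
    if want_x:
        out["x"] = []
    for eps in eps_list:
        res, status, rounds = solve_once(eps)
        if res is None:
            out["status"] = "solver_status_%d" % status
            break
        t = res.x[t_col]
        out["bounds"].append(float(-res.fun))
        out["rounds"].append(rounds)
        out["t"].append(float(t))
        if want_x:
            x = res.x[: n * n] / t if t > 0 else res.x[: n * n] * 0.0
            out["x"].append([float(v) for v in x])
    with open(out_path, "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
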