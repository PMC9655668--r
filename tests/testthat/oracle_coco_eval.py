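"""Independent COCO-protocol AP oracle used by the R test suite.

Reads a JSON file {"gt": [...], "dt": [...]} (each entry: image_id,
category_id, bbox [x, y, w, h], and score for detections), computes the
COCO metrics (IoU 0.5:0.05:0.95, 101-point interpolation, area splits at
32^2 / 96^2, 100 detections per image) with numpy, and writes a JSON object
{AP, AP50, AP75, APS, APM, APL} on the 0-100 scale.
"""
import json
import sys

import numpy as np

IOU_THRS = np.arange(0.5, 0.951, 0.05)
REC_THRS = np.linspace(0, 1, 101)
AREAS = {"all": (0, float("inf")), "small": (0, 32 ** 2),
         "medium": (32 ** 2, 96 ** 2), "large": (96 ** 2, float("inf"))}
MAXDET = 100


def box_iou(d, g):
    if len(d) == 0 or len(g) == 0:
        return np.zeros((len(d), len(g)))
    d = np.asarray(d, float)
    g = np.asarray(g, float)
    ix = np.maximum(0, np.minimum(d[:, None, 0] + d[:, None, 2],
                                  g[None, :, 0] + g[None, :, 2])
                    - np.maximum(d[:, None, 0], g[None, :, 0]))
    iy = np.maximum(0, np.minimum(d[:, None, 1] + d[:, None, 3],
                                  g[None, :, 1] + g[None, :, 3])
                    - np.maximum(d[:, None, 1], g[None, :, 1]))
    inter = ix * iy
    un = (d[:, None, 2] * d[:, None, 3] + g[None, :, 2] * g[None, :, 3]
          - inter)
    return np.where(un > 0, inter / un, 0)


def eval_img(dts, gts, arng):
    if not dts and not gts:
        return None
    g_ig = np.array([a["bbox"][2] * a["bbox"][3] < arng[0]
                     or a["bbox"][2] * a["bbox"][3] > arng[1]
                     for a in gts], bool)
    order_g = np.argsort(g_ig, kind="stable")
    gts = [gts[i] for i in order_g]
    g_ig = g_ig[order_g]
    dts = sorted(dts, key=lambda x: -x["score"])[:MAXDET]
    iou = box_iou([d["bbox"] for d in dts], [g["bbox"] for g in gts])
    nT, nd, ng = len(IOU_THRS), len(dts), len(gts)
    dtm = np.zeros((nT, nd), int)
    dt_ig = np.zeros((nT, nd), bool)
    gtm = np.zeros((nT, ng), int)
    for t, thr in enumerate(IOU_THRS):
        for d in range(nd):
            best = thr - 1e-10
            m = -1
            for g in range(ng):
                if gtm[t, g] > 0:
                    continue
                if m > -1 and not g_ig[m] and g_ig[g]:
                    break
                if iou[d, g] < best:
                    continue
                best = iou[d, g]
                m = g
            if m > -1:
                dtm[t, d] = m + 1
                gtm[t, m] = d + 1
                dt_ig[t, d] = g_ig[m]
            else:
                a = dts[d]["bbox"][2] * dts[d]["bbox"][3]
                dt_ig[t, d] = a < arng[0] or a > arng[1]
    return {"score": np.array([d["score"] for d in dts]),
            "dtm": dtm, "dt_ig": dt_ig, "npig": int((~g_ig).sum())}


def accumulate(gt, dt):
    cats = sorted({a["category_id"] for a in gt})
    imgs = sorted({a["image_id"] for a in gt} | {a["image_id"] for a in dt})
    ap = np.full((len(IOU_THRS), len(AREAS), len(cats)), np.nan)
    for ci, cat in enumerate(cats):
        for ai, arng in enumerate(AREAS.values()):
            evs = []
            for im in imgs:
                e = eval_img([d for d in dt if d["image_id"] == im
                              and d["category_id"] == cat],
                             [g for g in gt if g["image_id"] == im
                              and g["category_id"] == cat], arng)
                if e is not None:
                    evs.append(e)
            if not evs:
                continue
            npig = sum(e["npig"] for e in evs)
            if npig == 0:
                continue
            scores = np.concatenate([e["score"] for e in evs])
            order = np.argsort(-scores, kind="mergesort")
            for t in range(len(IOU_THRS)):
                dtm = np.concatenate([e["dtm"][t] for e in evs])[order]
                ig = np.concatenate([e["dt_ig"][t] for e in evs])[order]
                tp = np.cumsum((dtm > 0) & ~ig)
                fp = np.cumsum((dtm == 0) & ~ig)
                rc = tp / npig
                pr = tp / np.maximum(tp + fp, np.finfo(float).eps)
                pr = np.maximum.accumulate(pr[::-1])[::-1]
                inds = np.searchsorted(rc, REC_THRS, side="left")
                q = np.zeros(len(REC_THRS))
                ok = inds < len(pr)
                q[ok] = pr[inds[ok]]
                ap[t, ai, ci] = q.mean()
    def m(ts, ai):
        v = ap[ts][:, ai, :] if isinstance(ts, slice) else ap[ts, ai, :]
        v = v[~np.isnan(v)]
        return float(v.mean() * 100) if v.size else 0.0
    return {"AP": m(slice(None), 0),
            "AP50": m(0, 0), "AP75": m(5, 0),
            "APS": m(slice(None), 1), "APM": m(slice(None), 2),
            "APL": m(slice(None), 3)}


def main():
    with open(sys.argv[1]) as fh:
        data = json.load(fh)
    res = accumulate(data["gt"], data["dt"])
    with open(sys.argv[2], "w") as fh:
        json.dump(res, fh)


if __name__ == "__main__":
    main()
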