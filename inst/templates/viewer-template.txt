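<!DOCTYPE html>
<html>
<head>
<meta charset="utf-8">
<title>chemspace3d scene viewer</title>
<style>
  body { margin: 0; background: #111; color: #ddd; font: 13px sans-serif; }
  #info { position: fixed; top: 8px; left: 8px; background: rgba(0,0,0,.7);
          padding: 6px 10px; border-radius: 4px; max-width: 40em;
          pointer-events: none; }
  canvas { display: block; }
</style>
</head>
<body>
<div id="info">drag to rotate &middot; wheel to zoom &middot; hover a point</div>
<canvas id="cv"></canvas>
<script id="scene-data" type="application/json">__SCENE_JSON__</script>
<script>
"use strict";
var scene = JSON.parse(document.getElementById("scene-data").textContent);
var cv = document.getElementById("cv"), ctx = cv.getContext("2d");
var info = document.getElementById("info");
var N = scene.grid.n_bins, half = N / 2;
var pts = scene.points.map(function (p) {
  return { x: p.cell[0] - half, y: p.cell[1] - half, z: p.cell[2] - half,
           col: "rgb(" + p.rgb.join(",") + ")",
           label: p.member_ids.join(", ") + " | " + p.smiles };
});
var oc = scene.overlay_color ? "rgb(" + scene.overlay_color.join(",") + ")" : "rgb(148,0,211)";
scene.overlay_points.forEach(function (p) {
  pts.push({ x: p.cell[0] - half, y: p.cell[1] - half, z: p.cell[2] - half,
             col: oc, label: "[overlay] " + p.id + " " + (p.name || "") });
});
var rotX = -0.4, rotY = 0.6, zoom = 2.2, drag = null, proj = [];
function resize() { cv.width = innerWidth; cv.height = innerHeight; draw(); }
function draw() {
  ctx.fillStyle = "#111"; ctx.fillRect(0, 0, cv.width, cv.height);
  var cx = cv.width / 2, cy = cv.height / 2;
  var sy = Math.sin(rotY), cyr = Math.cos(rotY);
  var sx = Math.sin(rotX), cxr = Math.cos(rotX);
  proj = [];
  for (var i = 0; i < pts.length; i++) {
    var p = pts[i];
    var x1 = p.x * cyr + p.z * sy, z1 = -p.x * sy + p.z * cyr;
    var y1 = p.y * cxr - z1 * sx, z2 = p.y * sx + z1 * cxr;
    var s = 600 / (600 + z2 * zoom);
    var px = cx + x1 * zoom * s, py = cy - y1 * zoom * s;
    var r = Math.max(1.2, 2.6 * s);
    ctx.fillStyle = p.col;
    ctx.beginPath(); ctx.arc(px, py, r, 0, 6.2832); ctx.fill();
    proj.push([px, py, i]);
  }
}
cv.addEventListener("mousedown", function (e) { drag = [e.clientX, e.clientY]; });
addEventListener("mouseup", function () { drag = null; });
addEventListener("mousemove", function (e) {
  if (drag) {
    rotY += (e.clientX - drag[0]) * 0.008;
    rotX += (e.clientY - drag[1]) * 0.008;
    drag = [e.clientX, e.clientY]; draw(); return;
  }
  var best = null, bd = 64;
  for (var i = 0; i < proj.length; i++) {
    var dx = proj[i][0] - e.clientX, dy = proj[i][1] - e.clientY;
    var d = dx * dx + dy * dy;
    if (d < bd) { bd = d; best = proj[i][2]; }
  }
  info.textContent = best === null ?
    scene.fingerprint + " space, " + pts.length + " points (" +
      scene.descriptor + ")" : pts[best].label;
});
cv.addEventListener("wheel", function (e) {
  zoom *= e.deltaY < 0 ? 1.1 : 0.9; draw(); e.preventDefault();
});
addEventListener("resize", resize);
resize();
</script>
</body>
</html>
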